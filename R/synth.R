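# Synthetic benchmark universes: background/promoter stand-ins,
# G/C-matched negatives, and peak sets with motifs implanted under
# controlled co-occurrence regimes.  Everything is reproducible from a
# single integer seed; the caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

random_seqs <- function(n, length, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  length <- rep_len(length, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length[[i]], replace = TRUE,
                 prob = p), collapse = ""),
    character(1))
}

#' Generate an i.i.d. background sequence set
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1-gc)/2.  Used both as a promoter/calibration
#' stand-in and as raw material for peak sets.
#'
#' @param n number of sequences.
#' @param length sequence length in bp (recycled over sequences).
#' @param gc target G/C fraction in `[0, 1]` (default 0.5).
#' @param seed integer seed (NULL: use the current RNG state).
#' @param label role label for the resulting [sequence_set()].
#' @param prefix id prefix.
#' @return a [sequence_set()].
#' @export
gen_background <- function(n, length, gc = 0.5, seed = NULL,
                           label = "promoter", prefix = "bg") {
  stopifnot(n >= 1, all(length >= 1), gc >= 0, gc <= 1)
  seqs <- with_seed(seed, random_seqs(n, length, gc))
  names(seqs) <- paste0(prefix, "_", seq_len(n))
  sequence_set(seqs, label = label)
}

#' Generate G/C- and length-matched negative sequences
#'
#' For each positive sequence (peak), draws `per_peak` random sequences
#' of identical length whose G/C fraction matches the peak's within
#' `gc_tol` (candidates are re-drawn until the tolerance is met; after
#' `max_tries` draws the closest candidate is kept).  This emulates
#' sampling genome background by length and G/C content.  The default
#' `per_peak = 5` gives the recommended 1:5 positive:negative ratio.
#'
#' @param positives the positive [sequence_set()].
#' @param per_peak negatives per peak (default 5).
#' @param gc_tol per-pair G/C tolerance (default 0.02).
#' @param seed integer seed.
#' @param max_tries candidate draws before settling for the closest.
#' @return a [sequence_set()] of `per_peak * length(positives)`
#'   sequences, labelled `"negative"`.
#' @export
gen_negatives <- function(positives, per_peak = 5, gc_tol = 0.02,
                          seed = NULL, max_tries = 200L) {
  stopifnot(per_peak >= 1)
  lens <- nchar(unclass(positives))
  gcs <- gc_fraction(positives)
  ids <- names(positives)
  seqs <- with_seed(seed, {
    out <- character(length(positives) * per_peak)
    k <- 0L
    for (i in seq_along(positives)) {
      for (j in seq_len(per_peak)) {
        best <- NULL
        best_d <- Inf
        for (try in seq_len(max_tries)) {
          cand <- random_seqs(1L, lens[[i]], gcs[[i]])
          d <- abs(gc_fraction(cand) - gcs[[i]])
          if (d < best_d) {
            best <- cand
            best_d <- d
          }
          if (best_d <= gc_tol) break
        }
        k <- k + 1L
        out[[k]] <- best
      }
    }
    out
  })
  names(seqs) <- paste0(rep(ids, each = per_peak), "_neg",
                        rep(seq_len(per_peak), length(positives)))
  sequence_set(seqs, label = "negative")
}

#' Motif implantation regime
#'
#' Describes how two motifs are distributed over a peak set:
#' \describe{
#'   \item{`independent`}{each peak receives motif A with probability
#'     `rate_a` and motif B with probability `rate_b`, independently.}
#'   \item{`cooccur`}{one coin per peak: either both motifs are
#'     implanted (probability `rate_a`) or neither.}
#'   \item{`exclusive`}{a peak receives A only (probability `rate_a`),
#'     B only (`rate_b`) or nothing; never both.}
#' }
#'
#' @param kind one of `"independent"`, `"cooccur"`, `"exclusive"`.
#' @param motif_a,motif_b consensus strings (implanted verbatim) or
#'   [motif_matrix()] objects (instances sampled column-wise from the
#'   base frequencies).
#' @param rate_a,rate_b per-peak implantation probabilities in `[0, 1]`
#'   (`rate_b` defaults to `rate_a`; for `"exclusive"`,
#'   `rate_a + rate_b` must not exceed 1).
#' @return an object of class `implant_regime`.
#' @export
implant_regime <- function(kind = c("independent", "cooccur", "exclusive"),
                           motif_a, motif_b, rate_a = 0.5,
                           rate_b = rate_a) {
  kind <- match.arg(kind)
  stopifnot(rate_a >= 0, rate_a <= 1, rate_b >= 0, rate_b <= 1)
  if (kind == "exclusive" && rate_a + rate_b > 1)
    stop("exclusive regime needs rate_a + rate_b <= 1")
  if (kind == "cooccur" && rate_b != rate_a)
    warning("cooccur regime uses a single rate; rate_b ignored")
  structure(list(kind = kind, motif_a = motif_a, motif_b = motif_b,
                 rate_a = rate_a, rate_b = rate_b),
            class = "implant_regime")
}

motif_instance_fun <- function(motif) {
  if (is.character(motif)) {
    m <- toupper(motif)
    list(length = nchar(m), draw = function() m)
  } else if (inherits(motif, "motif_matrix")) {
    f <- freq_columns(motif)
    L <- nrow(f)
    list(length = L, draw = function()
      paste(vapply(seq_len(L), function(i)
        sample(c("A", "C", "G", "T"), 1L, prob = f[i, ]), character(1)),
        collapse = ""))
  } else stop("motif must be a consensus string or a motif_matrix")
}

#' Implant two motifs into a peak set under a regime
#'
#' For each peak, implantation indicators for motifs A and B are drawn
#' according to the regime; each implanted instance is placed at a
#' uniformly random offset on a uniformly random strand (minus-strand
#' instances are reverse-complemented) and overwrites the background at
#' that offset, preserving peak length.  When one peak receives both
#' motifs (independent regime) the second placement avoids overlapping
#' the first.
#'
#' @param peaks a [sequence_set()] of background peaks.
#' @param regime an [implant_regime()].
#' @param seed integer seed.
#' @return list with `sequences` (the implanted [sequence_set()],
#'   labelled `"positive"`) and `truth` (data.frame with columns
#'   `seq_id`, `motif` (`"A"`/`"B"`), `offset` (1-based start on the
#'   forward strand), `strand`).
#' @export
implant <- function(peaks, regime, seed = NULL) {
  stopifnot(inherits(regime, "implant_regime"))
  fa <- motif_instance_fun(regime$motif_a)
  fb <- motif_instance_fun(regime$motif_b)
  lens <- nchar(unclass(peaks))
  if (any(lens < max(fa$length, fb$length)))
    stop("motif longer than a peak")
  n <- length(peaks)
  with_seed(seed, {
    ind <- switch(regime$kind,
      independent = cbind(a = stats::runif(n) < regime$rate_a,
                          b = stats::runif(n) < regime$rate_b),
      cooccur = {
        u <- stats::runif(n) < regime$rate_a
        cbind(a = u, b = u)
      },
      exclusive = {
        u <- stats::runif(n)
        cbind(a = u < regime$rate_a,
              b = u >= regime$rate_a & u < regime$rate_a + regime$rate_b)
      })
    seqs <- unclass(peaks)
    truth <- list()
    for (i in seq_len(n)) {
      placed <- NULL  # occupied interval of the first implant
      for (which in c("A", "B")) {
        if (!ind[i, tolower(which)]) next
        gen <- if (which == "A") fa else fb
        inst <- gen$draw()
        L <- gen$length
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") inst <- revcomp(inst)
        offs <- seq_len(lens[[i]] - L + 1L)
        if (!is.null(placed))
          offs <- offs[offs + L - 1L < placed[[1L]] | offs > placed[[2L]]]
        if (length(offs) == 0L) next  # no non-overlapping slot; skip
        off <- offs[[sample.int(length(offs), 1L)]]
        substr(seqs[[i]], off, off + L - 1L) <- inst
        if (is.null(placed)) placed <- c(off, off + L - 1L)
        truth[[length(truth) + 1L]] <-
          data.frame(seq_id = names(peaks)[[i]], motif = which,
                     offset = off, strand = strand)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seq_id = character(0), motif = character(0),
                 offset = integer(0), strand = character(0))
    list(sequences = sequence_set(stats::setNames(seqs, names(peaks)),
                                  label = "positive"),
         truth = truth)
  })
}

#' Gaussian score profiles for direct PR-curve exercise
#'
#' Draws raw recognition scores directly, bypassing sequence scanning:
#' negative-set scores from N(5, 2.5) and positive-set scores from an
#' equal mixture of N(10, 1) (sites passing a stringent threshold) and
#' N(5.5, 4) (sites failing it).
#'
#' @param nf,nb positive and negative sample sizes.
#' @param seed integer seed.
#' @return list with numeric vectors `positive` and `negative`.
#' @export
gen_gaussian_profiles <- function(nf, nb, seed = NULL) {
  stopifnot(nf >= 1, nb >= 1)
  with_seed(seed, {
    comp <- stats::runif(nf) < 0.5
    pos <- ifelse(comp, stats::rnorm(nf, 10, 1), stats::rnorm(nf, 5.5, 4))
    neg <- stats::rnorm(nb, 5, 2.5)
    list(positive = pos, negative = neg)
  })
}

#' Generate a complete synthetic benchmark universe
#'
#' Convenience wrapper producing everything one pipeline run needs:
#' a promoter/calibration stand-in, a peak set with motifs implanted
#' under the given regime, matched negatives, and the implantation
#' truth table.
#'
#' @param regime an [implant_regime()].
#' @param n_peaks number of peaks (default 500).
#' @param peak_length peak length in bp (default 300).
#' @param per_peak negatives per peak (default 5).
#' @param n_promoters,promoter_length calibration stand-in dimensions
#'   (defaults 200 x 3000 bp).
#' @param gc background G/C fraction (default 0.5).
#' @param seed integer seed driving all four generators.
#' @return list with `positive`, `negative`, `promoters`
#'   ([sequence_set()]s) and `truth` (data.frame).
#' @export
gen_universe <- function(regime, n_peaks = 500, peak_length = 300,
                         per_peak = 5, n_promoters = 200,
                         promoter_length = 3000, gc = 0.5, seed = NULL) {
  seeds <- if (is.null(seed)) vector("list", 4L) else
    as.list(seed + 0:3)
  promoters <- gen_background(n_promoters, promoter_length, gc,
                              seed = seeds[[1L]], label = "promoter",
                              prefix = "prom")
  raw_peaks <- gen_background(n_peaks, peak_length, gc, seed = seeds[[2L]],
                              label = "positive", prefix = "peak")
  imp <- implant(raw_peaks, regime, seed = seeds[[3L]])
  negatives <- gen_negatives(imp$sequences, per_peak = per_peak,
                             seed = seeds[[4L]])
  list(positive = imp$sequences, negative = negatives,
       promoters = promoters, truth = imp$truth)
}
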