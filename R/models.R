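#' Build a position weight matrix from a count matrix
#'
#' Converts per-position base counts into additive log-odds weights
#' against a background base composition:
#' \deqn{w_{i,b} = \ln\frac{(n_{i,b} + p\,q_b)/(N_i + p)}{q_b}}
#' where \eqn{n_{i,b}} is the count of base \eqn{b} at position \eqn{i},
#' \eqn{N_i} the row sum, \eqn{p} the pseudocount and \eqn{q_b} the
#' background probability of base \eqn{b}.  A window score is the sum of
#' the weights of its bases; windows containing N are unscoreable.
#'
#' @param x a [motif_matrix()] or a bare numeric L x 4 count matrix
#'   (columns A, C, G, T).
#' @param pseudocount positive regularizer, distributed over bases in
#'   proportion to the background (default 1).
#' @param background base probabilities (A, C, G, T); must sum to 1.
#'   Default uniform.
#' @param name motif name (defaults to the matrix name).
#' @return an object of class `pwm`: list with `name`, `weights`
#'   (L x 4), `length`, `background`, `score_range = c(min, max)`.
#' @export
build_pwm <- function(x, pseudocount = 1, background = rep(0.25, 4),
                      name = NULL) {
  if (inherits(x, "motif_matrix")) {
    if (is.null(name)) name <- x$name
    counts <- x$counts
  } else {
    counts <- as.matrix(x)
    if (is.null(name)) name <- "pwm"
  }
  if (ncol(counts) != 4L) stop("count matrix must be L x 4")
  if (nrow(counts) < 1L) stop("empty count matrix")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 strictly positive probabilities")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1")
  rs <- rowSums(counts)
  if (any(rs <= 0)) stop("all-zero row in count matrix")
  bg <- matrix(background, nrow(counts), 4L, byrow = TRUE)
  w <- log((counts + pseudocount * bg) / (rs + pseudocount) / bg)
  dimnames(w) <- list(NULL, c("A", "C", "G", "T"))
  structure(list(name = name,
                 weights = w,
                 length = nrow(w),
                 background = background,
                 score_range = c(sum(apply(w, 1L, min)),
                                 sum(apply(w, 1L, max)))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm \"", x$name, "\": ", x$length, " positions, score range [",
      format(x$score_range[[1L]], digits = 4), ", ",
      format(x$score_range[[2L]], digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Model length (scanning window width)
#'
#' @param model a scoring model (`pwm` or `external_scores`).
#' @return integer window length.
#' @export
model_length <- function(model) UseMethod("model_length")

#' @export
model_length.pwm <- function(model) model$length

#' @export
model_length.external_scores <- function(model) model$length

#' Model name
#' @param model a scoring model.
#' @return character name.
#' @export
model_name <- function(model) UseMethod("model_name")

#' @export
model_name.pwm <- function(model) model$name

#' @export
model_name.external_scores <- function(model) model$name

#' Score a single window with a PWM
#'
#' @param model a [build_pwm()] object.
#' @param window a string of exactly `model$length` bases.
#' @return the additive log-odds score, or `NA` if the window contains N.
#' @export
window_score <- function(model, window) {
  stopifnot(inherits(model, "pwm"))
  codes <- encode_dna(toupper(window))
  if (length(codes) != model$length)
    stop("window length ", length(codes), " != model length ", model$length)
  if (anyNA(codes)) return(NA_real_)
  sum(model$weights[cbind(seq_len(model$length), codes)])
}

# Window scores of a PWM along one strand of an encoded sequence.
# Returns numeric(0) if the sequence is shorter than the motif;
# NA where the window covers an N.
pwm_scan_codes <- function(weights, codes) {
  L <- nrow(weights)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  w <- weights[1L, ]
  acc <- w[codes[seq_len(n)]]
  if (L > 1L) for (i in 2:L) {
    w <- weights[i, ]
    acc <- acc + w[codes[i:(i + n - 1L)]]
  }
  unname(acc)
}

# --- uniform scanning contract -------------------------------------------
# scan_all(model, seqs):  every defined window score over both strands,
#   as one flat numeric vector (N windows dropped; they count in neither
#   the numerator nor the denominator of ERR).
# scan_best(model, seqs): per-sequence best score over both strands,
#   -Inf when no window is scoreable (short or all-N sequences).

scan_all <- function(model, seqs) UseMethod("scan_all")

scan_best <- function(model, seqs) UseMethod("scan_best")

#' @export
scan_all.pwm <- function(model, seqs) {
  out <- lapply(unclass(seqs), function(s) {
    codes <- encode_dna(s)
    c(pwm_scan_codes(model$weights, codes),
      pwm_scan_codes(model$weights, revcomp_codes(codes)))
  })
  flat <- unlist(out, use.names = FALSE)
  flat[!is.na(flat)]
}

#' @export
scan_best.pwm <- function(model, seqs) {
  vapply(unclass(seqs), function(s) {
    codes <- encode_dna(s)
    sc <- c(pwm_scan_codes(model$weights, codes),
            pwm_scan_codes(model$weights, revcomp_codes(codes)))
    sc <- sc[!is.na(sc)]
    if (length(sc) == 0L) -Inf else max(sc)
  }, numeric(1))
}

# --- external (precomputed) score models ---------------------------------

#' Load precomputed per-position scores as a scoring model
#'
#' Supports motif models whose recognition function is not a PWM (for
#' example dinucleotide-feature models trained elsewhere): the model is
#' represented by a table of precomputed window scores over a fixed
#' sequence set.  Positions absent from the table are treated as
#' unscoreable (like N-containing windows).
#'
#' @param path TSV with columns `seq_id`, `strand` (`+`/`-`), `offset`
#'   (0-based window start on the given strand) and `score`; a header
#'   line is optional.
#' @param seqs the [sequence_set()] the scores refer to.
#' @param length window length of the underlying model, in bp.
#' @param name model name.
#' @return an object of class `external_scores`.
#' @export
load_external_scores <- function(path, seqs, length, name = "external") {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("^seq_id\\b", first)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           comment.char = "#",
                           col.names = c("seq_id", "strand", "offset", "score"),
                           colClasses = c("character", "character",
                                          "integer", "numeric"))
  external_scores(tab, seqs, length = length, name = name)
}

#' @rdname load_external_scores
#' @param table a data.frame with columns `seq_id`, `strand`, `offset`,
#'   `score` (used directly instead of reading from a file).
#' @export
external_scores <- function(table, seqs, length, name = "external") {
  length <- as.integer(length)
  if (length < 1L) stop("model length must be >= 1")
  ids <- names(seqs)
  unknown <- setdiff(unique(table$seq_id), ids)
  if (base::length(unknown))
    stop("score table names unknown sequence id: ", unknown[[1L]])
  if (!all(table$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  lens <- nchar(unclass(seqs))[match(table$seq_id, ids)]
  bad <- table$offset < 0L | table$offset > (lens - length)
  if (any(bad))
    stop("offset out of range for sequence ", table$seq_id[bad][[1L]])
  structure(list(name = name, length = length,
                 table = table[c("seq_id", "strand", "offset", "score")]),
            class = "external_scores")
}

#' Query one precomputed window score
#'
#' @param model an [external_scores()] model.
#' @param seq_id,strand,offset window address (0-based offset).
#' @return the tabulated score, or `NA` if the window is not listed.
#' @export
external_score <- function(model, seq_id, strand, offset) {
  stopifnot(inherits(model, "external_scores"))
  hit <- model$table$seq_id == seq_id & model$table$strand == strand &
    model$table$offset == offset
  if (!any(hit)) return(NA_real_)
  model$table$score[hit][[1L]]
}

#' @export
scan_all.external_scores <- function(model, seqs) {
  keep <- model$table$seq_id %in% names(seqs)
  model$table$score[keep]
}

#' @export
scan_best.external_scores <- function(model, seqs) {
  ids <- names(seqs)
  best <- rep(-Inf, length(ids))
  names(best) <- ids
  if (nrow(model$table)) {
    agg <- tapply(model$table$score, model$table$seq_id, max)
    hit <- intersect(names(agg), ids)
    best[hit] <- agg[hit]
  }
  best
}

#' @export
print.external_scores <- function(x, ...) {
  cat("external_scores \"", x$name, "\": window ", x$length, " bp, ",
      nrow(x$table), " tabulated position(s)\n", sep = "")
  invisible(x)
}
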