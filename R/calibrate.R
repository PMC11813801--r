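#' Threshold-vs-ERR calibration table
#'
#' Scans a scoring model over a reference sequence set (typically the
#' promoters of all genes of a genome, or a stand-in) at every position
#' on both strands and tabulates, for each observed score threshold, the
#' expected recognition rate (ERR): the fraction of scanned positions
#' whose score is greater than or equal to the threshold.  ERR puts
#' heterogeneous models (PWM, external) on one common stringency scale.
#'
#' Windows containing N are excluded from both the numerator and the
#' denominator.  The table is truncated at `err_ceiling`: thresholds so
#' mild that more than that fraction of reference positions pass are
#' never useful for recognition and are not stored.
#'
#' @param model a scoring model ([build_pwm()] or [external_scores()]).
#' @param reference the calibration [sequence_set()].
#' @param err_ceiling truncation point of the table (default 0.02).
#' @param n_grid `NULL` to use every distinct observed score as a
#'   threshold (exact; the default), or an integer number of
#'   quantile-grid thresholds for very large calibration sets.
#' @return an object of class `err_table`: list with `threshold`
#'   (decreasing), `err` (increasing, aligned), `n_positions`,
#'   `model_name`, `err_ceiling`.
#' @export
err_table <- function(model, reference, err_ceiling = 0.02, n_grid = NULL) {
  if (err_ceiling <= 0 || err_ceiling > 1)
    stop("err_ceiling must be in (0, 1]")
  scores <- scan_all(model, reference)
  n <- length(scores)
  if (n == 0L)
    stop("calibration set too small: no scoreable windows")
  ss <- sort(scores, decreasing = TRUE)
  if (is.null(n_grid)) {
    r <- rle(ss)
    thr <- r$values
    err <- cumsum(r$lengths) / n
  } else {
    stopifnot(n_grid >= 2L)
    thr <- unique(stats::quantile(ss, probs = seq(1, 0, length.out = n_grid),
                                  names = FALSE, type = 1L))
    err <- vapply(thr, function(t) sum(ss >= t) / n, numeric(1))
    keep <- !duplicated(err)
    thr <- thr[keep]
    err <- err[keep]
  }
  keep <- err <= err_ceiling
  if (!any(keep))
    warning("no usable thresholds: every threshold exceeds the ERR ceiling")
  structure(list(threshold = thr[keep],
                 err = err[keep],
                 n_positions = n,
                 model_name = model_name(model),
                 err_ceiling = err_ceiling),
            class = "err_table")
}

#' @export
print.err_table <- function(x, ...) {
  cat("err_table for \"", x$model_name, "\": ", length(x$threshold),
      " threshold(s), ", x$n_positions, " scanned positions, ceiling ",
      x$err_ceiling, "\n", sep = "")
  if (length(x$threshold))
    cat("  ERR range: ", format(x$err[[1L]], digits = 4), " - ",
        format(x$err[[length(x$err)]], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Convert raw scores to the ERR scale
#'
#' Step-function lookup: a score is mapped to the ERR of the most
#' stringent tabulated threshold it reaches.  Scores below every
#' tabulated threshold (i.e. milder than the table ceiling) map to
#' `Inf`, the "above ceiling" sentinel.
#'
#' @param table an [err_table()].
#' @param score numeric vector of raw model scores.
#' @return numeric vector of ERR values (with `Inf` for above-ceiling).
#' @export
score_to_err <- function(table, score) {
  stopifnot(inherits(table, "err_table"))
  out <- rep(Inf, length(score))
  if (length(table$threshold) == 0L) return(out)
  asc_thr <- rev(table$threshold)
  asc_err <- rev(table$err)
  j <- findInterval(score, asc_thr)
  ok <- !is.na(j) & j >= 1L
  out[ok] <- asc_err[j[ok]]
  out[is.na(score)] <- Inf
  out
}

#' Usable ERR thresholds under an analysis bound
#'
#' Returns the tabulated ERR values strictly below `errmax`, in
#' increasing order; these are the thresholds that participate in a
#' partial PR curve bounded at `errmax`.
#'
#' @param table an [err_table()].
#' @param errmax analysis bound on the expected recognition rate
#'   (strict: ties at exactly `errmax` are excluded).
#' @return increasing numeric vector (possibly empty).
#' @export
thresholds_under <- function(table, errmax) {
  stopifnot(inherits(table, "err_table"), errmax > 0, errmax <= 1)
  sort(table$err[table$err < errmax])
}

#' Write / read an ERR table as TSV
#'
#' Two tab-separated columns `threshold`, `err` preceded by a comment
#' line recording the model name, the number of scanned positions and
#' the ceiling, so the table round-trips losslessly.
#'
#' @param table an [err_table()].
#' @param path file path.
#' @return `path` (write) or an [err_table()] (read).
#' @export
write_err_table <- function(table, path) {
  stopifnot(inherits(table, "err_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model=%s n_positions=%d err_ceiling=%s",
                     table$model_name, table$n_positions,
                     sprintf("%.17g", table$err_ceiling)), con)
  writeLines("threshold\terr", con)
  if (length(table$threshold))
    writeLines(sprintf("%.17g\t%.17g", table$threshold, table$err), con)
  invisible(path)
}

#' @rdname write_err_table
#' @export
read_err_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  meta <- lines[[1L]]
  get_meta <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[^ ]+"), meta))
    sub(paste0(key, "="), "", m)
  }
  body <- lines[-(1:2)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    thr <- vapply(parts, function(p) as.numeric(p[[1L]]), numeric(1))
    err <- vapply(parts, function(p) as.numeric(p[[2L]]), numeric(1))
  } else {
    thr <- numeric(0)
    err <- numeric(0)
  }
  structure(list(threshold = thr, err = err,
                 n_positions = as.integer(get_meta("n_positions")),
                 model_name = get_meta("model"),
                 err_ceiling = as.numeric(get_meta("err_ceiling"))),
            class = "err_table")
}

#' Calibrate a motif against a reference set
#'
#' Convenience constructor pairing a scoring model with its ERR table.
#' When `x` is a count matrix, the PWM background defaults to the
#' mononucleotide composition of the calibration set, so that scoring
#' and calibration share the same null.
#'
#' @param x a [motif_matrix()], [build_pwm()] or [external_scores()]
#'   object.
#' @param reference the calibration [sequence_set()].
#' @param err_ceiling,n_grid passed to [err_table()].
#' @param pseudocount PWM pseudocount (count-matrix input only).
#' @param background PWM background; default is the composition of
#'   `reference` (count-matrix input only).
#' @return an object of class `calibrated_motif`: list with `model`,
#'   `table` and (when available) the source `matrix`.
#' @export
calibrate <- function(x, reference, err_ceiling = 0.02, n_grid = NULL,
                      pseudocount = 1, background = NULL) {
  mat <- NULL
  if (inherits(x, "motif_matrix")) {
    mat <- x
    if (is.null(background)) background <- base_composition(reference)
    model <- build_pwm(x, pseudocount = pseudocount, background = background)
  } else if (inherits(x, "pwm") || inherits(x, "external_scores")) {
    model <- x
  } else {
    stop("cannot calibrate object of class ", class(x)[[1L]])
  }
  tab <- err_table(model, reference, err_ceiling = err_ceiling,
                   n_grid = n_grid)
  structure(list(model = model, table = tab, matrix = mat),
            class = "calibrated_motif")
}

#' @export
print.calibrated_motif <- function(x, ...) {
  cat("calibrated_motif \"", model_name(x$model), "\"\n", sep = "")
  print(x$model)
  print(x$table)
  invisible(x)
}

#' Mononucleotide composition of a sequence set
#'
#' @param seqs a [sequence_set()] or character vector.
#' @return probabilities of A, C, G, T (N excluded), as a 4-vector.
#' @export
base_composition <- function(seqs) {
  counts <- integer(4)
  for (s in unclass(seqs)) {
    codes <- encode_dna(s)
    tab <- tabulate(codes[!is.na(codes)], nbins = 4L)
    counts <- counts + tab
  }
  if (sum(counts) == 0L) stop("no A/C/G/T characters in set")
  stats::setNames(counts / sum(counts), c("A", "C", "G", "T"))
}
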