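#' Best-hit recognition profile of a motif over a sequence set
#'
#' Reduces every sequence to the ERR of its best motif hit: the highest
#' window score over both strands, mapped through the model's
#' Threshold-vs-ERR table.  Small ERR means a stringent, specific hit.
#' Sequences with no scoreable window (shorter than the motif, or
#' all N) and sequences whose best score falls below the table ceiling
#' get the sentinel `Inf` ("above ceiling", never recognized).
#'
#' @param x a [calibrated_motif()], or a scoring model when `table` is
#'   given separately.
#' @param seqs the [sequence_set()] to profile.
#' @param table an [err_table()] for `x` (ignored when `x` is already
#'   calibrated).
#' @param set_label role label stored on the profile; defaults to the
#'   label of `seqs`.
#' @return an object of class `recognition_profile`: a named numeric
#'   vector of best-hit ERRs, index-aligned to `seqs`, with attributes
#'   `motif_label` and `set_label`.
#' @export
recognition_profile <- function(x, seqs, table = NULL, set_label = NULL) {
  if (inherits(x, "calibrated_motif")) {
    model <- x$model
    table <- x$table
  } else {
    model <- x
    if (is.null(table)) stop("an err_table is required")
  }
  if (is.null(set_label)) set_label <- attr(seqs, "label")
  best <- scan_best(model, seqs)
  err <- score_to_err(table, best)
  names(err) <- names(seqs)
  structure(err,
            motif_label = model_name(model),
            set_label = set_label,
            class = "recognition_profile")
}

#' @export
print.recognition_profile <- function(x, ...) {
  cat("recognition_profile \"", attr(x, "motif_label"), "\" over ",
      length(x), " sequence(s)",
      if (!is.null(attr(x, "set_label")))
        paste0(" [", attr(x, "set_label"), "]"),
      "\n", sep = "")
  cat("  recognized below ceiling: ", sum(is.finite(x)), "/", length(x),
      "\n", sep = "")
  invisible(x)
}

#' Construct a recognition profile from best-hit ERR values
#'
#' Wraps a bare numeric vector of per-sequence best-hit ERRs (with
#' `Inf` as the above-ceiling sentinel) as a [recognition_profile()].
#' Useful for external pipelines and for exercising the PR-curve layer
#' directly.
#'
#' @param x numeric vector of best-hit ERRs in `(0, 1]` or `Inf`.
#' @param motif_label,set_label profile annotation.
#' @return a [recognition_profile()].
#' @export
err_profile <- function(x, motif_label = "profile", set_label = NULL) {
  if (inherits(x, "recognition_profile")) return(x)
  x <- as.numeric(x)
  if (any(x <= 0, na.rm = TRUE))
    stop("best-hit ERR values must be positive")
  structure(x,
            motif_label = motif_label, set_label = set_label,
            class = "recognition_profile")
}

#' Joint-motif profile: recognize A or B
#'
#' The joint motif A&B is recognized in a sequence at a given ERR
#' threshold when at least one of the two single motifs is recognized
#' there, i.e. the joint best-hit ERR is the elementwise minimum of the
#' single best-hit ERRs.
#'
#' @param a,b [recognition_profile()]s aligned to the same sequence set.
#' @return a [recognition_profile()] labelled `"A&B"`.
#' @export
joint_profile <- function(a, b) {
  if (length(a) != length(b))
    stop("profiles have different lengths (", length(a), " vs ",
         length(b), ")")
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b)))
    stop("profiles are aligned to different sequence sets")
  structure(pmin(unclass(a), unclass(b)),
            names = names(a),
            motif_label = paste0(attr(a, "motif_label"), "&",
                                 attr(b, "motif_label")),
            set_label = attr(a, "set_label"),
            class = "recognition_profile")
}

#' Fraction of sequences recognized under an ERR bound
#'
#' @param profile a [recognition_profile()].
#' @param errmax strict upper bound on the best-hit ERR.
#' @return fraction in `[0, 1]`.
#' @export
recognized_fraction <- function(profile, errmax) {
  stopifnot(errmax > 0, errmax <= 1)
  mean(unclass(profile) < errmax)
}

#' Write recognition profiles as a diagnostic TSV
#'
#' One row per sequence, one column of best-hit ERRs per motif;
#' above-ceiling sentinels are written as `Inf`.
#'
#' @param profiles named list of aligned [recognition_profile()]s.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(length(profiles) >= 1L)
  n <- unique(vapply(profiles, length, integer(1)))
  if (length(n) != 1L) stop("profiles have different lengths")
  ids <- names(profiles[[1L]])
  if (is.null(ids)) ids <- as.character(seq_len(n))
  labs <- names(profiles)
  if (is.null(labs))
    labs <- vapply(profiles, attr, character(1), "motif_label")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("seq_id", labs), collapse = "\t"), con)
  body <- do.call(cbind, lapply(profiles, function(p)
    sprintf("%.17g", unclass(p))))
  writeLines(paste(ids, apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}
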