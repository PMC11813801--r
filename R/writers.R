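#' Write PR curves to a TSV file
#'
#' One header line, then one block of rows per curve in the given order
#' (for a pair analysis: A, B, joint).  Columns: `curve_label`,
#' `threshold_ERR`, `Recall`, `Precision`; curve points are written at
#' full precision.  An empty curve contributes zero data lines and a
#' warning.
#'
#' @param curves a named list of [pr_curve()]s, or a `pair_result`
#'   (whose three curves are written in A, B, joint order).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pr_curves <- function(curves, path) {
  if (inherits(curves, "pair_result")) {
    labs <- c(curves$motifs, paste(curves$motifs, collapse = "&"))
    curves <- stats::setNames(curves$curves, labs)
  }
  stopifnot(length(curves) >= 1L)
  labs <- names(curves)
  if (is.null(labs))
    labs <- vapply(curves, function(cv) {
      ml <- attr(cv, "motif_label")
      if (is.null(ml)) "curve" else ml
    }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("curve_label\tthreshold_ERR\tRecall\tPrecision", con)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    if (nrow(cv) == 0L) {
      warning("curve \"", labs[[i]], "\" is empty (no threshold under ",
              "ERRMAX); writing no data lines for it")
      next
    }
    writeLines(sprintf("%s\t%.17g\t%.17g\t%.17g", labs[[i]],
                       cv$err_threshold, cv$TPR, cv$PREC), con)
  }
  invisible(path)
}

#' Write a pair-analysis report
#'
#' Key-value TSV with the pAUPRC of both single motifs and of the joint
#' motif, the RAUC, and the similarity screen; scalars are printed with
#' four decimal places.
#'
#' @param result a `pair_result` from [pair_analysis()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pair_report <- function(result, path) {
  stopifnot(inherits(result, "pair_result"))
  fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)
  sim_score <- if (is.null(result$similarity)) NA_real_ else
    result$similarity$score
  sim_flag <- if (is.null(result$similarity)) "not_assessed" else
    result$similarity$flag
  lines <- c(
    paste0("pAUPRC_A\t", fmt(result$pauprc[["A"]])),
    paste0("pAUPRC_B\t", fmt(result$pauprc[["B"]])),
    paste0("pAUPRC_joint\t", fmt(result$pauprc[["joint"]])),
    paste0("RAUC\t", fmt(result$rauc)),
    paste0("similarity_score\t", fmt(sim_score)),
    paste0("similarity_flag\t", sim_flag))
  writeLines(lines, path)
  invisible(path)
}

#' Write the RAUC (or similarity) matrix of a collection analysis
#'
#' @param x a `pair_matrix` from [all_pairs()] or [top_k_pairs()].
#' @param path output file path.
#' @param what which matrix to write: `"rauc"`, `"pauprc_joint"` or
#'   `"similarity"`.
#' @return `path`, invisibly.
#' @export
write_pair_matrix <- function(x, path, what = c("rauc", "pauprc_joint",
                                                "similarity")) {
  stopifnot(inherits(x, "pair_matrix"))
  what <- match.arg(what)
  m <- x[[what]]
  if (is.null(m)) stop("matrix \"", what, "\" was not computed")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("motif", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[[i]],
                       ifelse(is.na(m[i, ]), "NA",
                              sprintf("%.4f", m[i, ]))),
                     collapse = "\t"), con)
  invisible(path)
}
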