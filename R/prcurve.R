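#' Corrected precision
#'
#' Precision computed from the recognized fractions rather than the raw
#' counts: \eqn{PREC = TPR / (TPR + FPR)}.  With counts this equals
#' \eqn{TP / (TP + FP \cdot NF/NB)}; the NF/NB coefficient removes the
#' dependence on the negative:positive set-size ratio, so that a
#' no-skill model (identical score distributions in both sets) sits at
#' precision 0.5 regardless of how many negatives were sampled per peak.
#'
#' @param tpr,fpr recognized fractions of the positive and negative
#'   sets, in `[0, 1]`.  Vectorized.
#' @return corrected precision in `[0, 1]`; `NA` where both rates are 0
#'   (such thresholds carry no prediction and are skipped upstream).
#' @export
corrected_precision <- function(tpr, fpr) {
  stopifnot(all(tpr >= 0 & tpr <= 1), all(fpr >= 0 & fpr <= 1))
  out <- tpr / (tpr + fpr)
  out[tpr == 0 & fpr == 0] <- NA_real_
  out
}

#' Partial corrected precision-recall curve
#'
#' Builds the PR curve of a motif from its best-hit ERR profiles over
#' the positive (peak) and negative (background) sets.  The threshold
#' grid is the union of best-hit ERR values observed in either profile,
#' restricted to `ERR < errmax` (strict); at each threshold t a sequence
#' counts as predicted when its best-hit ERR is <= t.  Thresholds where
#' nothing is predicted are dropped.  Precision is the corrected
#' precision ([corrected_precision()]).  For the integral a virtual
#' origin at recall 0 carries the precision of the first real point.
#'
#' @param pos,neg [recognition_profile()]s of the positive and negative
#'   sets (bare numeric vectors of best-hit ERRs are accepted).
#' @param errmax partial-area bound on the expected recognition rate
#'   (default 0.002; the recommended range is 0.001 to 0.01).
#' @return an object of class `pr_curve`: a data.frame with columns
#'   `err_threshold`, `TP`, `FP`, `TPR`, `FPR`, `PREC` and attributes
#'   `NF`, `NB`, `errmax`, `origin_prec`.
#' @export
pr_curve <- function(pos, neg, errmax = 0.002) {
  stopifnot(errmax > 0, errmax <= 1)
  pv <- as.numeric(unclass(pos))
  nv <- as.numeric(unclass(neg))
  nf <- length(pv)
  nb <- length(nv)
  stopifnot(nf >= 1L, nb >= 1L)
  grid <- sort(unique(c(pv[is.finite(pv)], nv[is.finite(nv)])))
  grid <- grid[grid < errmax]
  sp <- sort(pv)
  sn <- sort(nv)
  tp <- findInterval(grid, sp)
  fp <- findInterval(grid, sn)
  keep <- tp + fp > 0L
  grid <- grid[keep]
  tp <- tp[keep]
  fp <- fp[keep]
  tpr <- tp / nf
  fpr <- fp / nb
  prec <- corrected_precision(tpr, fpr)
  pts <- data.frame(err_threshold = grid, TP = tp, FP = fp,
                    TPR = tpr, FPR = fpr, PREC = prec)
  if (nrow(pts) == 0L)
    warning("empty PR curve: no recognition threshold under ERRMAX")
  structure(pts,
            NF = nf, NB = nb, errmax = errmax,
            origin_prec = if (nrow(pts)) prec[[1L]] else NA_real_,
            motif_label = attr(pos, "motif_label"),
            class = c("pr_curve", "data.frame"))
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("pr_curve", if (!is.null(attr(x, "motif_label")))
    paste0(" \"", attr(x, "motif_label"), "\""),
    ": ", nrow(x), " point(s), NF = ", attr(x, "NF"),
    ", NB = ", attr(x, "NB"), ", ERRMAX = ", attr(x, "errmax"),
    "\n", sep = "")
  if (nrow(x)) {
    cat("  final recall ", format(x$TPR[[nrow(x)]], digits = 4),
        ", precision range [", format(min(x$PREC), digits = 4), ", ",
        format(max(x$PREC), digits = 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Partial area under the corrected PR curve (pAUPRC)
#'
#' Trapezoid sum over the curve points with the no-skill baseline 0.5
#' subtracted and the factor 2 restoring a maximum of 1:
#' \deqn{pAUPRC = 2 \sum_i \left\{\frac{PREC_i + PREC_{i-1}}{2} - 0.5\right\}
#'   (REC_i - REC_{i-1})}
#' with the virtual origin \eqn{(REC_0, PREC_0) = (0, PREC_1)}.  A
#' perfect classifier (all positives recognized under ERRMAX, no
#' negatives) scores exactly 1; a no-skill model scores 0; negative
#' values signal selection toward the negative set and are reported as
#' is, not clamped.
#'
#' @param curve a [pr_curve()].
#' @return the partial area (0 for an empty curve).
#' @export
pauprc <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  if (nrow(curve) == 0L) return(0)
  prec <- c(attr(curve, "origin_prec"), curve$PREC)
  rec <- c(0, curve$TPR)
  n <- length(rec)
  sum(2 * ((prec[-1L] + prec[-n]) / 2 - 0.5) * diff(rec))
}

#' Ratio of areas under curves (RAUC)
#'
#' \deqn{RAUC = pAUPRC(A\&B) / \max\{pAUPRC(A), pAUPRC(B)\}}
#' RAUC > 1 means the joint motif outperforms both singles, the
#' signature of mutually exclusive occurrence of the two motifs.
#'
#' @param pauprc_a,pauprc_b single-motif partial areas.
#' @param pauprc_joint joint-motif partial area.
#' @return the ratio, or `NA` when `max(pauprc_a, pauprc_b) <= 0`.
#' @export
rauc <- function(pauprc_a, pauprc_b, pauprc_joint) {
  m <- max(pauprc_a, pauprc_b)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  pauprc_joint / m
}
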