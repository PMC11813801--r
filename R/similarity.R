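#' PWM similarity screen
#'
#' A high RAUC is only evidence of mutually exclusive occurrence when
#' the two motifs are genuinely different; near-identical matrices
#' trivially "improve" on each other.  This screen aligns the two
#' frequency matrices over every relative offset and both orientations
#' (the second matrix is also tried reverse-complemented), requiring an
#' overlap of at least `min_overlap` columns, and scores each placement
#' by the mean column-wise Pearson correlation of the base-frequency
#' 4-vectors.  The score is the maximum over placements.
#'
#' A column with zero variance (flat frequencies) correlates 1 with an
#' equal column and 0 with anything else.
#'
#' @param a,b [motif_matrix()] objects or bare L x 4 count matrices.
#' @param min_overlap minimum aligned columns; default
#'   `min(4, min(LA, LB))`.
#' @param score_threshold similarity score at or above which the pair
#'   may be flagged redundant (default 0.9).
#' @param overlap_frac minimum best-placement overlap, as a fraction of
#'   the shorter motif, for the redundant flag (default 0.75).
#' @return list with `score`, `overlap` (columns at the best placement),
#'   `orientation` (`"forward"` or `"revcomp"`) and `flag`
#'   (`"redundant"` or `"distinct"`).
#' @export
pwm_similarity <- function(a, b, min_overlap = NULL,
                           score_threshold = 0.9, overlap_frac = 0.75) {
  fa <- freq_columns(a)
  fb <- freq_columns(b)
  la <- nrow(fa)
  lb <- nrow(fb)
  if (is.null(min_overlap)) min_overlap <- min(4L, la, lb)
  best <- list(score = -Inf, overlap = 0L, orientation = "forward")
  for (orient in c("forward", "revcomp")) {
    fbb <- if (orient == "forward") fb else revcomp_matrix(fb)
    for (shift in seq.int(-(lb - min_overlap), la - min_overlap)) {
      ia <- max(1L, 1L + shift):min(la, lb + shift)
      ib <- ia - shift
      ov <- length(ia)
      if (ov < min_overlap) next
      sc <- mean(vapply(seq_len(ov), function(t)
        col_cor(fa[ia[[t]], ], fbb[ib[[t]], ]), numeric(1)))
      if (sc > best$score ||
          (sc == best$score && ov > best$overlap)) {
        best <- list(score = sc, overlap = ov, orientation = orient)
      }
    }
  }
  best$flag <- if (best$score >= score_threshold &&
                   best$overlap >= overlap_frac * min(la, lb))
    "redundant" else "distinct"
  best
}

freq_columns <- function(x) {
  counts <- if (inherits(x, "motif_matrix")) x$counts else as.matrix(x)
  if (ncol(counts) != 4L) stop("motif matrix must be L x 4")
  counts / rowSums(counts)
}

# reverse complement of an L x 4 frequency matrix: reverse the rows and
# swap A<->T, C<->G
revcomp_matrix <- function(f) {
  f[rev(seq_len(nrow(f))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

# Pearson correlation of two frequency 4-vectors with a deterministic
# zero-variance convention.
col_cor <- function(u, v) {
  su <- stats::sd(u)
  sv <- stats::sd(v)
  if (su == 0 || sv == 0)
    return(if (max(abs(u - v)) < 1e-12) 1 else 0)
  stats::cor(u, v)
}
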