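#' Analyze one motif pair for mutually exclusive occurrence
#'
#' The central analysis: profile both calibrated motifs over the
#' positive (ChIP-seq peak) and negative (background) sets, form the
#' joint A&B motif (recognized where at least one single motif is), and
#' compare partial PR-curve areas.  RAUC > 1 flags pairs whose joint
#' motif outperforms both singles — the two motifs tend to occur in
#' different peaks (mutual exclusivity); a similarity screen guards
#' against the trivial explanation that A and B are the same motif.
#'
#' @param a,b [calibrate()]d motifs.
#' @param positive,negative [sequence_set()]s of peaks and background.
#' @param errmax partial-area ERR bound (default 0.002).
#' @param similarity compute the PWM similarity screen when both count
#'   matrices are available (default TRUE).
#' @return an object of class `pair_result`: list with `motifs`,
#'   `pauprc` (named A/B/joint), `rauc`, `recognized` (fractions of
#'   peaks recognized under `errmax`), `similarity` (list
#'   `score`, `overlap`, `flag` or NULL), `curves` (list of three
#'   [pr_curve()]s), `NF`, `NB`, `errmax`.
#' @seealso [all_pairs()], [one_vs_collection()], [top_k_pairs()]
#' @export
pair_analysis <- function(a, b, positive, negative, errmax = 0.002,
                          similarity = TRUE) {
  stopifnot(inherits(a, "calibrated_motif"), inherits(b, "calibrated_motif"))
  pa_pos <- recognition_profile(a, positive, set_label = "positive")
  pa_neg <- recognition_profile(a, negative, set_label = "negative")
  pb_pos <- recognition_profile(b, positive, set_label = "positive")
  pb_neg <- recognition_profile(b, negative, set_label = "negative")
  pair_from_profiles(pa_pos, pa_neg, pb_pos, pb_neg, errmax = errmax,
                     similarity = if (similarity) list(a = a$matrix,
                                                       b = b$matrix))
}

#' Pair analysis from precomputed recognition profiles
#'
#' The profile-level core of [pair_analysis()], exposed for workflows
#' where best-hit ERR profiles are produced elsewhere (external score
#' models, simulation studies): builds the three PR curves (A, B,
#' joint) and the pAUPRC/RAUC summary.
#'
#' @param pa_pos,pa_neg positive/negative-set [recognition_profile()]s
#'   of motif A (bare ERR vectors are accepted).
#' @param pb_pos,pb_neg the same for motif B.
#' @param errmax partial-area ERR bound.
#' @param similarity optional list with elements `a`, `b`: the two
#'   [motif_matrix()] objects for the similarity screen.
#' @return a `pair_result` (see [pair_analysis()]).
#' @export
pair_from_profiles <- function(pa_pos, pa_neg, pb_pos, pb_neg,
                               errmax = 0.002, similarity = NULL) {
  pa_pos <- err_profile(pa_pos, "A")
  pa_neg <- err_profile(pa_neg, "A")
  pb_pos <- err_profile(pb_pos, "B")
  pb_neg <- err_profile(pb_neg, "B")
  pj_pos <- joint_profile(pa_pos, pb_pos)
  pj_neg <- joint_profile(pa_neg, pb_neg)
  curves <- list(
    A = suppressWarnings(pr_curve(pa_pos, pa_neg, errmax)),
    B = suppressWarnings(pr_curve(pb_pos, pb_neg, errmax)),
    joint = suppressWarnings(pr_curve(pj_pos, pj_neg, errmax)))
  p <- vapply(curves, pauprc, numeric(1))
  sim <- NULL
  if (!is.null(similarity) && !is.null(similarity$a) &&
      !is.null(similarity$b))
    sim <- pwm_similarity(similarity$a, similarity$b)
  structure(list(
    motifs = c(attr(pa_pos, "motif_label"), attr(pb_pos, "motif_label")),
    pauprc = c(A = p[["A"]], B = p[["B"]], joint = p[["joint"]]),
    rauc = rauc(p[["A"]], p[["B"]], p[["joint"]]),
    recognized = c(A = recognized_fraction(pa_pos, errmax),
                   B = recognized_fraction(pb_pos, errmax),
                   joint = recognized_fraction(pj_pos, errmax)),
    similarity = sim,
    curves = curves,
    NF = length(pa_pos), NB = length(pa_neg),
    errmax = errmax), class = "pair_result")
}

#' @export
print.pair_result <- function(x, digits = 4, ...) {
  cat("Joint-motif PR analysis: ", x$motifs[[1L]], " + ", x$motifs[[2L]],
      "\n", sep = "")
  cat("  NF = ", x$NF, ", NB = ", x$NB, ", ERRMAX = ", x$errmax, "\n",
      sep = "")
  cat("  pAUPRC: A = ", format(x$pauprc[["A"]], digits = digits),
      ", B = ", format(x$pauprc[["B"]], digits = digits),
      ", joint = ", format(x$pauprc[["joint"]], digits = digits),
      "\n", sep = "")
  cat("  RAUC = ", format(x$rauc, digits = digits),
      if (is.finite(x$rauc) && x$rauc > 1)
        "  (joint motif outperforms both singles)", "\n", sep = "")
  if (!is.null(x$similarity))
    cat("  similarity = ", format(x$similarity$score, digits = digits),
        " [", x$similarity$flag, "]\n", sep = "")
  invisible(x)
}

#' @export
summary.pair_result <- function(object, ...) {
  print(object, ...)
  cat("  recognized fraction of peaks under ERRMAX: A = ",
      format(object$recognized[["A"]], digits = 3), ", B = ",
      format(object$recognized[["B"]], digits = 3), ", joint = ",
      format(object$recognized[["joint"]], digits = 3), "\n", sep = "")
  for (lab in names(object$curves)) {
    cv <- object$curves[[lab]]
    cat("  curve ", lab, ": ", nrow(cv), " point(s)",
        if (nrow(cv)) paste0(", final recall ",
                             format(cv$TPR[[nrow(cv)]], digits = 3)),
        "\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.pair_result <- function(object, ...) {
  c(pAUPRC_A = unname(object$pauprc[["A"]]),
    pAUPRC_B = unname(object$pauprc[["B"]]),
    pAUPRC_joint = unname(object$pauprc[["joint"]]),
    RAUC = object$rauc)
}

#' Plot the three PR curves of a pair analysis
#'
#' Recall on the x axis, corrected precision on the y axis; single
#' motifs in red/blue, the joint motif in black; the no-skill baseline
#' 0.5 dashed.
#'
#' @param x a `pair_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pair_result <- function(x, ...) {
  cols <- c(A = "red3", B = "blue3", joint = "black")
  xmax <- max(c(0.05, vapply(x$curves, function(cv)
    if (nrow(cv)) max(cv$TPR) else 0, numeric(1))))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "Recall", ylab = "Corrected precision",
                 main = paste(x$motifs, collapse = " / "), ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  for (lab in names(x$curves)) {
    cv <- x$curves[[lab]]
    if (!nrow(cv)) next
    graphics::lines(c(0, cv$TPR), c(attr(cv, "origin_prec"), cv$PREC),
                    col = cols[[lab]],
                    lwd = if (lab == "joint") 2.5 else 1.5)
  }
  graphics::legend("bottomleft",
                   legend = c(x$motifs, paste(x$motifs, collapse = "&")),
                   col = cols, lwd = c(1.5, 1.5, 2.5), bty = "n")
  invisible(x)
}

# profiles for every motif of a named list of calibrated motifs
collection_profiles <- function(motifs, seqs, set_label) {
  lapply(motifs, function(m)
    recognition_profile(m, seqs, set_label = set_label))
}

#' All-pairs analysis of a motif collection
#'
#' Evaluates all K(K-1)/2 unordered pairs of a collection; single-motif
#' profiles and pAUPRC values are computed once and reused.
#'
#' @param motifs named list of [calibrate()]d motifs (K >= 2, unique
#'   names).
#' @param positive,negative [sequence_set()]s of peaks and background.
#' @param errmax partial-area ERR bound.
#' @param similarity compute pairwise PWM similarity where matrices are
#'   available.
#' @return an object of class `pair_matrix`: list with `motifs` (names),
#'   `pauprc_single` (named vector), `pauprc_joint`, `rauc` and
#'   `similarity` (K x K symmetric matrices; `rauc` diagonal is 1
#'   wherever the single pAUPRC is positive), `errmax`.
#' @export
all_pairs <- function(motifs, positive, negative, errmax = 0.002,
                      similarity = TRUE) {
  k <- length(motifs)
  stopifnot(k >= 2L)
  nm <- names(motifs)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("motifs must have unique non-empty names")
  pos_prof <- collection_profiles(motifs, positive, "positive")
  neg_prof <- collection_profiles(motifs, negative, "negative")
  single <- vapply(nm, function(i)
    pauprc(suppressWarnings(pr_curve(pos_prof[[i]], neg_prof[[i]], errmax))),
    numeric(1))
  pj <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  ra <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  sm <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    cvj <- suppressWarnings(pr_curve(
      joint_profile(pos_prof[[i]], pos_prof[[j]]),
      joint_profile(neg_prof[[i]], neg_prof[[j]]), errmax))
    pj[i, j] <- pj[j, i] <- pauprc(cvj)
    ra[i, j] <- ra[j, i] <- rauc(single[[i]], single[[j]], pj[i, j])
    if (similarity && !is.null(motifs[[i]]$matrix) &&
        !is.null(motifs[[j]]$matrix))
      sm[i, j] <- sm[j, i] <-
        pwm_similarity(motifs[[i]]$matrix, motifs[[j]]$matrix)$score
  }
  diag(pj) <- single
  diag(ra) <- ifelse(single > 0, 1, NA_real_)
  diag(sm) <- ifelse(vapply(motifs, function(m) !is.null(m$matrix),
                            logical(1)), 1, NA_real_)
  structure(list(motifs = nm, pauprc_single = single,
                 pauprc_joint = pj, rauc = ra,
                 similarity = if (similarity) sm,
                 errmax = errmax),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, digits = 3, ...) {
  cat("pair_matrix over ", length(x$motifs), " motif(s), ",
      length(x$motifs) * (length(x$motifs) - 1L) / 2L,
      " pair(s), ERRMAX = ", x$errmax, "\n", sep = "")
  cat("single-motif pAUPRC:\n")
  print(round(x$pauprc_single, digits))
  cat("RAUC:\n")
  print(round(x$rauc, digits))
  invisible(x)
}

#' One motif against a collection
#'
#' Pairs a query motif with every motif of a collection and ranks the
#' pairs by RAUC (descending), ties broken by joint pAUPRC then by
#' motif name.
#'
#' @param query a [calibrate()]d motif.
#' @param collection named list of [calibrate()]d motifs.
#' @param positive,negative,errmax,similarity as in [pair_analysis()].
#' @return an object of class `pair_ranking`: list with `ranking` (a
#'   data.frame with one row per collection motif, sorted) and `results`
#'   (the `pair_result` objects in ranked order).
#' @export
one_vs_collection <- function(query, collection, positive, negative,
                              errmax = 0.002, similarity = TRUE) {
  stopifnot(length(collection) >= 1L)
  nm <- names(collection)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("collection must have unique non-empty names")
  q_pos <- recognition_profile(query, positive, set_label = "positive")
  q_neg <- recognition_profile(query, negative, set_label = "negative")
  results <- lapply(nm, function(i) {
    m <- collection[[i]]
    pair_from_profiles(q_pos, q_neg,
                       recognition_profile(m, positive,
                                           set_label = "positive"),
                       recognition_profile(m, negative,
                                           set_label = "negative"),
                       errmax = errmax,
                       similarity = if (similarity)
                         list(a = query$matrix, b = m$matrix))
  })
  names(results) <- nm
  tab <- data.frame(
    motif = nm,
    pauprc_query = vapply(results, function(r) r$pauprc[["A"]], numeric(1)),
    pauprc_motif = vapply(results, function(r) r$pauprc[["B"]], numeric(1)),
    pauprc_joint = vapply(results, function(r) r$pauprc[["joint"]],
                          numeric(1)),
    rauc = vapply(results, function(r) r$rauc, numeric(1)),
    row.names = NULL)
  ord <- order(-xtfrm(tab$rauc), -xtfrm(tab$pauprc_joint), tab$motif)
  structure(list(query = model_name(query$model),
                 ranking = tab[ord, , drop = FALSE],
                 results = results[ord],
                 errmax = errmax),
            class = "pair_ranking")
}

#' @export
print.pair_ranking <- function(x, digits = 4, ...) {
  cat("one-vs-collection ranking for query \"", x$query, "\" (",
      nrow(x$ranking), " pair(s), ERRMAX = ", x$errmax, ")\n", sep = "")
  tab <- x$ranking
  tab[-1L] <- lapply(tab[-1L], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' All pairs among the top-k motifs of a collection
#'
#' Computes the single-motif pAUPRC for every motif of the collection,
#' keeps the k best (ties broken by motif name) and runs [all_pairs()]
#' on them.
#'
#' @param collection named list of [calibrate()]d motifs.
#' @param k number of motifs to keep (2 <= k <= length(collection)).
#' @param positive,negative,errmax,similarity as in [all_pairs()].
#' @return a `pair_matrix` (see [all_pairs()]) with an extra element
#'   `selected` naming the retained motifs in rank order.
#' @export
top_k_pairs <- function(collection, k, positive, negative,
                        errmax = 0.002, similarity = TRUE) {
  if (k < 2L) stop("k must be >= 2")
  if (k > length(collection)) stop("k exceeds the collection size")
  nm <- names(collection)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("collection must have unique non-empty names")
  single <- vapply(nm, function(i) {
    m <- collection[[i]]
    pauprc(suppressWarnings(pr_curve(
      recognition_profile(m, positive, set_label = "positive"),
      recognition_profile(m, negative, set_label = "negative"),
      errmax)))
  }, numeric(1))
  sel <- nm[order(-xtfrm(single), nm)][seq_len(k)]
  out <- all_pairs(collection[sel], positive, negative, errmax = errmax,
                   similarity = similarity)
  out$selected <- sel
  out
}
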