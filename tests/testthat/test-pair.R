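pair_fixture <- function(seed = 50) {
  reg <- implant_regime("exclusive", "ACGTACGT", "GGATCCAT", 0.5, 0.5)
  u <- gen_universe(reg, n_peaks = 60, peak_length = 200, per_peak = 3,
                    n_promoters = 30, promoter_length = 800, seed = seed)
  list(u = u,
       A = calibrate(consensus_counts("ACGTACGT"), u$promoters),
       B = calibrate(consensus_counts("GGATCCAT"), u$promoters))
}

test_that("pairing a motif with itself gives RAUC 1 and a redundant flag", {
  fx <- pair_fixture()
  res <- pair_analysis(fx$A, fx$A, fx$u$positive, fx$u$negative)
  expect_equal(res$rauc, 1.0)
  expect_equal(res$pauprc[["joint"]], res$pauprc[["A"]])
  expect_equal(res$similarity$score, 1.0)
  expect_equal(res$similarity$flag, "redundant")
})

test_that("pair_analysis summarises profiles, curves and areas", {
  fx <- pair_fixture()
  res <- pair_analysis(fx$A, fx$B, fx$u$positive, fx$u$negative)
  expect_s3_class(res, "pair_result")
  expect_equal(res$NF, 60L)
  expect_equal(res$NB, 180L)
  expect_named(res$pauprc, c("A", "B", "joint"))
  expect_equal(res$rauc, res$pauprc[["joint"]] / max(res$pauprc[["A"]],
                                                     res$pauprc[["B"]]))
  # joint recall extent dominates both singles
  last_rec <- vapply(res$curves, function(cv)
    if (nrow(cv)) max(cv$TPR) else 0, numeric(1))
  expect_gte(last_rec[["joint"]], max(last_rec[["A"]], last_rec[["B"]]))
  expect_gte(res$recognized[["joint"]],
             max(res$recognized[["A"]], res$recognized[["B"]]))
  expect_equal(res$similarity$flag, "distinct")
  # methods run
  expect_output(print(res), "RAUC")
  expect_named(coef(res), c("pAUPRC_A", "pAUPRC_B", "pAUPRC_joint", "RAUC"))
})

test_that("all_pairs evaluates K(K-1)/2 pairs symmetrically", {
  fx <- pair_fixture()
  coll <- list(m1 = fx$A, m2 = fx$B,
               m3 = calibrate(consensus_counts("TTGACGTC"),
                              fx$u$promoters))
  pm <- all_pairs(coll, fx$u$positive, fx$u$negative)
  expect_s3_class(pm, "pair_matrix")
  expect_equal(dim(pm$rauc), c(3L, 3L))
  off_diag <- pm$rauc[upper.tri(pm$rauc)]
  expect_length(off_diag, 3L)  # K(K-1)/2 with K = 3
  expect_equal(pm$rauc, t(pm$rauc))
  expect_equal(pm$pauprc_joint, t(pm$pauprc_joint))
  # diagonal is 1 wherever the single pAUPRC is positive
  pos_diag <- pm$pauprc_single > 0
  expect_true(all(diag(pm$rauc)[pos_diag] == 1))
  # each off-diagonal entry matches a standalone pair run
  res12 <- pair_analysis(coll$m1, coll$m2, fx$u$positive, fx$u$negative)
  expect_equal(pm$rauc["m1", "m2"], res12$rauc)
  expect_equal(pm$pauprc_single[["m1"]], res12$pauprc[["A"]])
})

test_that("all_pairs on a subset is a restriction of the full matrix", {
  fx <- pair_fixture()
  coll <- list(m1 = fx$A, m2 = fx$B,
               m3 = calibrate(consensus_counts("TTGACGTC"),
                              fx$u$promoters))
  pm_full <- all_pairs(coll, fx$u$positive, fx$u$negative)
  pm_sub <- all_pairs(coll[c("m1", "m3")], fx$u$positive, fx$u$negative)
  expect_equal(pm_sub$rauc["m1", "m3"], pm_full$rauc["m1", "m3"])
  expect_equal(pm_sub$pauprc_single, pm_full$pauprc_single[c("m1", "m3")])
})

test_that("one_vs_collection ranks all pairs by RAUC deterministically", {
  fx <- pair_fixture()
  coll <- list(mB = fx$B, self = fx$A,
               mC = calibrate(consensus_counts("TTGACGTC"),
                              fx$u$promoters))
  rk <- one_vs_collection(fx$A, coll, fx$u$positive, fx$u$negative)
  expect_s3_class(rk, "pair_ranking")
  # the ranking is a permutation of the collection
  expect_setequal(rk$ranking$motif, names(coll))
  expect_true(all(diff(rk$ranking$rauc) <= 0))
  # the self pair scores RAUC exactly 1
  expect_equal(rk$ranking$rauc[rk$ranking$motif == "self"], 1.0)
  # single-motif collection degenerates gracefully
  rk1 <- one_vs_collection(fx$A, coll["mB"], fx$u$positive, fx$u$negative)
  expect_equal(nrow(rk1$ranking), 1L)
})

test_that("top_k_pairs selects exactly the k best single motifs", {
  fx <- pair_fixture()
  coll <- list(good = fx$A, also_good = fx$B,
               weak = calibrate(consensus_counts("TTGACGTC"),
                                fx$u$promoters),
               weak2 = calibrate(consensus_counts("CCCTATAG"),
                                 fx$u$promoters))
  singles <- vapply(names(coll), function(i)
    pauprc(suppressWarnings(pr_curve(
      recognition_profile(coll[[i]], fx$u$positive),
      recognition_profile(coll[[i]], fx$u$negative), 0.002))),
    numeric(1))
  want <- names(sort(singles, decreasing = TRUE))[1:2]
  pm <- top_k_pairs(coll, 2, fx$u$positive, fx$u$negative)
  expect_setequal(pm$selected, want)
  expect_equal(dim(pm$rauc), c(2L, 2L))
  expect_error(top_k_pairs(coll, 1, fx$u$positive, fx$u$negative), ">= 2")
  expect_error(top_k_pairs(coll, 9, fx$u$positive, fx$u$negative),
               "exceeds")
  # k = collection size reproduces all_pairs
  pm_all <- top_k_pairs(coll, 4, fx$u$positive, fx$u$negative)
  expect_equal(pm_all$rauc,
               all_pairs(coll[pm_all$selected], fx$u$positive,
                         fx$u$negative)$rauc)
})

test_that("pair results and matrices serialize to their TSV formats", {
  fx <- pair_fixture()
  res <- pair_analysis(fx$A, fx$B, fx$u$positive, fx$u$negative)
  f1 <- tempfile(fileext = ".tsv")
  write_pair_report(res, f1)
  expect_length(readLines(f1), 6L)
  f2 <- tempfile(fileext = ".tsv")
  write_pr_curves(res, f2)
  lines <- readLines(f2)
  labs <- unique(vapply(strsplit(lines[-1], "\t"), `[[`, character(1), 1L))
  expect_equal(labs, c("ACGTACGT", "GGATCCAT", "ACGTACGT&GGATCCAT"))
  coll <- list(m1 = fx$A, m2 = fx$B)
  pm <- all_pairs(coll, fx$u$positive, fx$u$negative)
  f3 <- tempfile(fileext = ".tsv")
  write_pair_matrix(pm, f3, "rauc")
  expect_equal(readLines(f3)[[1L]], "motif\tm1\tm2")
})
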