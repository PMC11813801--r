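test_that("gen_background is seeded, composition-true and alphabet-clean", {
  a <- gen_background(20, 500, 0.5, seed = 7)
  b <- gen_background(20, 500, 0.5, seed = 7)
  expect_identical(unclass(a), unclass(b))
  c_ <- gen_background(20, 500, 0.5, seed = 8)
  expect_false(identical(unclass(a), unclass(c_)))
  # law of large numbers: observed G/C near the target
  expect_true(abs(mean(gc_fraction(a)) - 0.5) < 0.03)
  lo <- gen_background(20, 500, 0.2, seed = 9)
  expect_true(abs(mean(gc_fraction(lo)) - 0.2) < 0.03)
  # extreme compositions restrict the alphabet
  pure <- gen_background(5, 100, 1.0, seed = 10)
  expect_true(all(grepl("^[GC]+$", unclass(pure))))
})

test_that("gen_negatives matches length and G/C per peak", {
  peaks <- gen_background(30, 250, 0.45, seed = 11, label = "positive",
                          prefix = "peak")
  neg <- gen_negatives(peaks, per_peak = 5, seed = 12)
  expect_length(neg, 150L)
  expect_equal(attr(neg, "label"), "negative")
  # each block of 5 negatives mirrors its source peak
  for (i in seq_along(peaks)) {
    block <- unclass(neg)[(i - 1L) * 5L + 1:5]
    expect_true(all(nchar(block) == nchar(peaks[[i]])))
    expect_true(all(abs(gc_fraction(block) - gc_fraction(peaks[i]))
                    <= 0.02 + 1e-9))
  }
})

test_that("implantation regimes honour their truth-table contracts", {
  peaks <- gen_background(300, 120, 0.5, seed = 13, prefix = "pk")

  ex <- implant(peaks, implant_regime("exclusive", "ACGTACGT", "GGATCCAT",
                                      0.5, 0.5), seed = 14)
  by_peak <- table(ex$truth$seq_id, ex$truth$motif)
  expect_true(all(rowSums(by_peak > 0) <= 1))  # never both motifs

  co <- implant(peaks, implant_regime("cooccur", "ACGTACGT", "GGATCCAT",
                                      0.5), seed = 15)
  co_tab <- table(co$truth$seq_id, co$truth$motif)
  expect_true(all(rowSums(co_tab > 0) == 2))   # A and B coincide

  # implanted instances are really present at the recorded positions
  for (k in sample(nrow(ex$truth), 10)) {
    row <- ex$truth[k, ]
    motif <- if (row$motif == "A") "ACGTACGT" else "GGATCCAT"
    inst <- if (row$strand == "-") revcomp(motif) else motif
    expect_equal(substr(ex$sequences[[row$seq_id]], row$offset,
                        row$offset + 7L), inst)
  }
})

test_that("independent implantation hits the binomial expectation", {
  n <- 10000L
  peaks <- gen_background(n, 30, 0.5, seed = 16, prefix = "pk")
  imp <- implant(peaks, implant_regime("independent", "ACGTACGT",
                                       "GGATCCAT", 0.5, 0.5), seed = 17)
  both <- sum(table(imp$truth$seq_id) == 2L)
  # both-motif fraction within 3 sigma of 0.25 (four equally likely cases)
  sigma <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(both / n - 0.25), 3 * sigma)
})

test_that("implant validates motif length and preserves peak length", {
  peaks <- gen_background(5, 10, 0.5, seed = 18)
  expect_error(implant(peaks, implant_regime("independent",
                                             strrep("ACGT", 5), "ACGT", 1, 1),
                       seed = 1), "longer than a peak")
  imp <- implant(peaks, implant_regime("independent", "ACGT", "GGCC", 1, 1),
                 seed = 19)
  expect_equal(nchar(unclass(imp$sequences)), nchar(unclass(peaks)))
})

test_that("matrix-sampled implants draw from the column frequencies", {
  peaks <- gen_background(400, 40, 0.5, seed = 20)
  m <- consensus_counts("ACGTACGT")   # 97% consensus base per column
  imp <- implant(peaks, implant_regime("independent", m, "GGATCCAT",
                                       1, 0), seed = 21)
  hits <- imp$truth[imp$truth$motif == "A", ]
  inst <- vapply(seq_len(nrow(hits)), function(k) {
    s <- substr(imp$sequences[[hits$seq_id[[k]]]], hits$offset[[k]],
                hits$offset[[k]] + 7L)
    if (hits$strand[[k]] == "-") revcomp(s) else s
  }, character(1))
  match_frac <- mean(inst == "ACGTACGT")
  # P(exact consensus) = 0.97^8 ~ 0.78; allow generous sampling noise
  expect_gt(match_frac, 0.6)
  expect_lt(match_frac, 0.95)
})

test_that("regime constructor validates rates", {
  expect_error(implant_regime("exclusive", "AAAA", "CCCC", 0.7, 0.7),
               "rate_a \\+ rate_b")
  expect_warning(implant_regime("cooccur", "AAAA", "CCCC", 0.5, 0.3),
                 "rate_b ignored")
  expect_error(implant_regime("independent", "AAAA", "CCCC", 1.2))
})

test_that("gaussian score profiles match their stated distributions", {
  g <- gen_gaussian_profiles(10000, 10000, seed = 22)
  g2 <- gen_gaussian_profiles(10000, 10000, seed = 22)
  expect_identical(g, g2)
  expect_gt(mean(g$positive), mean(g$negative))  # 7.75 vs 5 in expectation
  expect_true(abs(mean(g$negative) - 5) < 0.1)
  expect_true(abs(mean(g$positive) - 7.75) < 0.15)
  # direct PR-curve exercise on the raw scores: convert scores to a
  # pseudo-ERR scale via the negative-set survival function
  sf <- stats::ecdf(-g$negative)
  pos_err <- sf(-g$positive)
  neg_err <- sf(-g$negative)
  pos_err[pos_err == 0] <- 1e-6
  neg_err[neg_err == 0] <- 1e-6
  cv <- pr_curve(err_profile(pos_err), err_profile(neg_err), errmax = 0.05)
  expect_true(all(cv$PREC > 0.5))  # real skill at stringent thresholds
  expect_gt(pauprc(cv), 0)
})

test_that("gen_universe wires the generators together reproducibly", {
  reg <- implant_regime("exclusive", "ACGTACGT", "GGATCCAT", 0.5, 0.5)
  u <- gen_universe(reg, n_peaks = 40, peak_length = 120, per_peak = 2,
                    n_promoters = 10, promoter_length = 400, seed = 23)
  expect_length(u$positive, 40L)
  expect_length(u$negative, 80L)
  expect_length(u$promoters, 10L)
  u2 <- gen_universe(reg, n_peaks = 40, peak_length = 120, per_peak = 2,
                     n_promoters = 10, promoter_length = 400, seed = 23)
  expect_identical(unclass(u$positive), unclass(u2$positive))
  expect_identical(u$truth, u2$truth)
  # negatives carry no implants: consensus occurrences stay at chance
  n_hits <- sum(vapply(unclass(u$negative), function(s)
    grepl("ACGTACGT", s, fixed = TRUE) ||
      grepl("ACGTACGT", revcomp(s), fixed = TRUE), logical(1)))
  expect_lt(n_hits / length(u$negative), 0.05)
})
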