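test_that("estimate_reporter_expression is the count-weighted bin mean", {
  expect_equal(estimate_reporter_expression(c(0, 0, 0, 25, 0, 0, 0, 0)),
               4)
  expect_equal(estimate_reporter_expression(c(10, 0, 0, 0, 0, 0, 0, 10)),
               4.5)
  set.seed(81)
  for (i in 1:10) {
    cnt <- rpois(8, 30)
    v <- sort(runif(8, 1, 100))
    expect_equal(estimate_reporter_expression(cnt, v),
                 sum(v * cnt) / sum(cnt))
    # invariant to scaling all counts
    expect_equal(estimate_reporter_expression(cnt * 7, v),
                 estimate_reporter_expression(cnt, v))
  }
  expect_true(is.na(estimate_reporter_expression(c(1, rep(0, 7)))))
})

test_that("wrt_compare matches the tie-corrected Wilcoxon on expanded data", {
  same <- wrt_compare(c(5, 5, 5, 5, 0, 0, 0, 0), c(5, 5, 5, 5, 0, 0, 0, 0))
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")

  ext <- wrt_compare(c(50, rep(0, 7)), c(rep(0, 7), 50))
  expect_lt(ext$p, 1e-10)
  expect_equal(ext$direction, "mut_higher")

  set.seed(82)
  for (i in 1:10) {
    w <- rpois(8, 10) + 1
    m <- rpois(8, 10) + 1
    got <- wrt_compare(w, m)
    xw <- rep(1:8, w)
    xm <- rep(1:8, m)
    ref <- suppressWarnings(
      stats::wilcox.test(xm, xw, exact = FALSE, correct = TRUE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    # symmetry: swapping groups preserves p and flips direction
    rev <- wrt_compare(m, w, min_reads = 1)
    expect_equal(rev$p, got$p, tolerance = 1e-12)
    if (got$direction != "none")
      expect_true(rev$direction != got$direction)
  }
})

test_that("wrt_compare normal approximation tracks exact enumeration", {
  # 3 vs 3 reads in distinct bins
  w <- c(1, 0, 1, 0, 1, 0, 0, 0)
  m <- c(0, 0, 0, 1, 0, 1, 0, 1)
  got <- wrt_compare(w, m, min_reads = 1)
  exact <- enumerate_mwu_p(c(1, 3, 5), c(4, 6, 8))
  expect_lt(abs(got$p - exact), 0.02)
})

test_that("wrt_compare downsamples totals above the read cap", {
  w <- c(0, 0, 2e4, 1e4, 0, 0, 0, 0)
  m <- c(0, 0, 1e4, 2e4, 0, 0, 0, 0)
  capped <- wrt_compare(w, m, read_cap = 3000)
  full <- wrt_compare(w, m, read_cap = 1e9)
  expect_equal(capped$direction, full$direction)
  expect_equal(sign(capped$z), sign(full$z))
  expect_lt(abs(capped$z), abs(full$z))  # less data, weaker evidence
})

test_that("bh_adjust reproduces step-up arithmetic", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_csr requires consistent per-replicate significance", {
  yes <- call_csr(c(0.01, 0.01, 0.04), rep("mut_higher", 3))
  expect_true(yes$csr)
  expect_equal(yes$direction, "repressive")

  expect_false(call_csr(c(0.01, 0.06, 0.01), rep("mut_higher", 3))$csr)
  expect_false(call_csr(c(0.01, 0.01, 0.01),
                        c("mut_higher", "wt_higher", "mut_higher"))$csr)
  enh <- call_csr(c(0.01, 0.02), rep("wt_higher", 2))
  expect_equal(enh$direction, "enhancing")
  # a missing replicate is tolerated if >= 2 informative ones qualify
  part <- call_csr(c(0.01, NA, 0.01), c("mut_higher", "none",
                                        "mut_higher"))
  expect_true(part$csr)
  expect_false(call_csr(c(0.01, NA, NA), c("mut_higher", "none",
                                           "none"))$csr)
})

test_that("uorf_effect and effect_ratio follow the worked-example arithmetic", {
  expect_equal(uorf_effect(1.0, 2.0), 0.5)
  expect_equal(uorf_effect(0.37, 0.75), 0.37 / 0.75)  # ~2-fold repression
  expect_equal(uorf_effect(3, 3), 1)
  expect_true(is.na(uorf_effect(0, 2)))

  er <- effect_ratio(0.28, 0.5)
  expect_equal(er$ratio, 0.56)
  expect_equal(er$modulation, "ded1_suppressed")
  expect_equal(effect_ratio(0.5, 0.5)$modulation, "neutral")
  up <- effect_ratio(0.8, 0.5)
  expect_equal(up$ratio, 1.6)
  expect_equal(up$modulation, "ded1_enhanced")
  expect_true(is.na(effect_ratio(NA, 0.5)$ratio))
})

test_that("summarize_library is calibrated on a small global-null library", {
  cfg <- facs_sim_config(n_uorfs = 60, frac_repressive = 0,
                         reads_per_reporter = 500,
                         cells_per_reporter = 2000)
  sim <- simulate_facs(cfg, seed = 91)
  res <- summarize_library(sim$bins, wt_strain = "DED1")
  expect_equal(res$cohort$n_uorfs, 60)
  expect_lt(abs(res$cohort$median_effect_ratio - 1), 0.05)
  expect_lt(abs(res$cohort$median_effect_wt_strain - 1), 0.05)
  expect_lte(res$cohort$n_csr_wt_strain + res$cohort$n_csr_mut_strain, 5)
})

test_that("true effects and null ratios are recovered on fluorescence bins", {
  cfg <- facs_sim_config(n_uorfs = 100, frac_repressive = 1,
                         repressive_effect = 0.5, effect_sdlog10 = 0)
  sim <- simulate_facs(cfg, seed = 92)
  res <- summarize_library(sim$bins, bin_values = sim$fluor_values,
                           wt_strain = "DED1")
  expect_lt(abs(res$cohort$median_effect_wt_strain - 0.5), 0.1)
  expect_lt(abs(res$cohort$median_effect_mut_strain - 0.5), 0.1)
  expect_lt(abs(res$cohort$median_effect_ratio - 1), 0.1)
})

test_that("stronger planted interactions yield weakly more suppressed calls", {
  n_supp <- vapply(c(1, 0.7, 0.5), function(r) {
    cfg <- facs_sim_config(n_uorfs = 150, frac_repressive = 0.5,
                           frac_suppressed = 0.3, suppressed_ratio = r)
    sim <- simulate_facs(cfg, seed = 93)
    res <- summarize_library(sim$bins, wt_strain = "DED1")
    sum(res$table$modulation == "ded1_suppressed", na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(n_supp) >= 0))
})

test_that("planted ded1-suppressed uORFs are recalled at the 1.33-fold rule", {
  cfg <- facs_sim_config(n_uorfs = 200, frac_repressive = 0.5,
                         frac_suppressed = 0.2, suppressed_ratio = 0.5)
  sim <- simulate_facs(cfg, seed = 94)
  res <- summarize_library(sim$bins, wt_strain = "DED1")
  m <- merge(res$table, sim$truth, by = "uorf_id")
  planted <- m[m$class == "ded1_suppressed" & !is.na(m$effect_ratio), ]
  recall <- mean(planted$modulation == "ded1_suppressed")
  expect_gte(recall, 0.8)
})

test_that("facs bin tables round-trip through TSV", {
  cfg <- facs_sim_config(n_uorfs = 3, n_replicates = 1,
                         reads_per_reporter = 100,
                         cells_per_reporter = 500)
  sim <- simulate_facs(cfg, seed = 95)
  path <- tempfile(fileext = ".tsv")
  write_facs_bins(sim$bins, path)
  back <- read_facs_bins(path)
  expect_equal(back, sim$bins)
})
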