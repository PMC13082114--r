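test_that("assign_psites offsets reads and conserves counts", {
  tr <- assign_psites(10L, 28L, transcript_length = 100)
  expect_equal(which(tr == 1) - 1, 22)
  expect_equal(sum(tr), 1)

  over <- assign_psites(95L, 28L, transcript_length = 100)
  expect_equal(sum(over), 0)
  expect_equal(attr(over, "dropped"), 1)

  set.seed(41)
  pos <- sample(0:99, 1000, replace = TRUE)
  len <- sample(25:34, 1000, replace = TRUE)
  tr2 <- assign_psites(pos, len, transcript_length = 100)
  expect_equal(sum(tr2), 1000 - attr(tr2, "dropped"))

  expect_error(assign_psites(1L, 20L, 100), "no offset")
  ok <- assign_psites(1L, 20L, 100, default_offset = 12)
  expect_equal(sum(ok), 1)
})

test_that("count_features applies the triplet and 20-codon exclusions", {
  tx <- toy_transcripts()
  uo <- toy_uorfs()
  # 5'UTR [0,30): first/last triplets excluded, only position 5 survives
  tr <- list(t1 = track_at(c(0, 1, 2, 5, 27, 28, 29), 400))
  cnt <- count_features(tr, tx, uo)
  expect_equal(unname(cnt["t1:utr5"]), 1)
  # mORF [30,330): 89 lies in the first 20 codons [30,90), 95 survives
  tr2 <- list(t1 = track_at(c(89, 95), 400))
  cnt2 <- count_features(tr2, tx, uo)
  expect_equal(unname(cnt2["t1:morf"]), 1)
  # uORF span counted in full; mRNA counting has no exclusions
  cnt_mrna <- count_features(tr, tx, uo, exclude = FALSE)
  expect_equal(unname(cnt_mrna["t1:utr5"]), 7)
  expect_equal(unname(cnt["t1_u1"]), 1)  # position 5 in [5,14)

  empty <- count_features(list(t1 = integer(400)), tx, uo)
  expect_true(all(empty == 0))
})

test_that("feature counts plus exclusion zones conserve total P-sites", {
  tx <- toy_transcripts()
  set.seed(17)
  for (i in 1:10) {
    tr <- list(t1 = track_at(sample(0:399, 200, replace = TRUE), 400))
    cnt <- count_features(tr, tx)
    tot <- sum(cnt[c("t1:utr5", "t1:morf", "t1:utr3")]) +
      sum(attr(cnt, "excluded"))
    expect_equal(tot, sum(tr$t1))
  }
})

test_that("short 5'UTRs are zeroed and flagged rather than erroring", {
  tx <- transcript_models(data.frame(
    transcript_id = "s1", utr5_start = 0L, utr5_end = 4L,
    morf_start = 4L, morf_end = 304L, utr3_start = 304L, utr3_end = 350L))
  tr <- list(s1 = track_at(c(0, 1, 2, 3), 350))
  cnt <- count_features(tr, tx)
  expect_equal(unname(cnt["s1:utr5"]), 0)
  expect_true("s1:utr5" %in% attr(cnt, "flags"))
})

test_that("size factors are median-of-ratios with geometric mean one", {
  sheet <- sample_sheet(c("A", "B"), c("WT", "MUT"), c("MRNA", "MRNA"),
                        c(1, 1))
  counts <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
                   dimnames = list(paste0("t", 1:3, ":morf"), c("A", "B")))
  expect_equal(unname(size_factors(feature_count_table(counts, sheet))),
               c(1, 1))

  counts2 <- counts
  counts2[, "B"] <- counts2[, "A"] * 2
  sf <- size_factors(feature_count_table(counts2, sheet))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  one <- sample_sheet("A", "WT", "MRNA", 1)
  counts1 <- counts[, "A", drop = FALSE]
  expect_equal(unname(size_factors(feature_count_table(counts1, one))), 1)
})

test_that("compute_te normalizes feature RPFs by host mORF mRNA", {
  tx <- toy_transcripts()
  uo <- toy_uorfs()
  sheet <- two_by_two_sheet()
  counts <- matrix(0, nrow = 4, ncol = 8,
                   dimnames = list(c("t1:utr5", "t1:morf", "t1:utr3",
                                     "t1_u1"), sheet$sample_id))
  counts["t1_u1", c("RPF_WT_1", "RPF_WT_2", "RPF_MUT_1", "RPF_MUT_2")] <- 8
  counts["t1:morf", ] <- 100
  fct <- feature_count_table(counts, sheet)
  sf <- stats::setNames(rep(1, 8), sheet$sample_id)

  te <- compute_te(fct, uo, sf = sf, pseudocount = 0)
  expect_equal(te$te_wt[te$feature_id == "t1_u1"], 0.08)

  # pseudocount rule: zero RPF still yields a finite TE
  counts0 <- counts
  counts0["t1_u1", ] <- 0
  te0 <- compute_te(feature_count_table(counts0, sheet), uo, sf = sf,
                    pseudocount = 0.5)
  expect_equal(te0$te_wt[te0$feature_id == "t1_u1"], 0.5 / 100.5)

  # genotype TE is the geometric mean of per-replicate ratios
  counts2 <- counts
  counts2["t1_u1", c("RPF_WT_1", "RPF_WT_2")] <- c(4, 16)
  te2 <- compute_te(feature_count_table(counts2, sheet), uo, sf = sf,
                    pseudocount = 0)
  expect_equal(te2$te_wt[te2$feature_id == "t1_u1"],
               sqrt(0.04 * 0.16))
})

test_that("filter_features enforces the 128-mRNA and 8-RPF thresholds", {
  tx <- toy_transcripts()
  uo <- toy_uorfs()
  sheet <- two_by_two_sheet()
  base <- matrix(0, nrow = 4, ncol = 8,
                 dimnames = list(c("t1:utr5", "t1:morf", "t1:utr3",
                                   "t1_u1"), sheet$sample_id))
  mrna_cols <- sheet$sample_id[sheet$assay == "MRNA"]
  rpf_cols <- sheet$sample_id[sheet$assay == "RPF"]

  at_127 <- base
  at_127["t1:morf", mrna_cols] <- c(32, 32, 32, 31)
  expect_false("t1:morf" %in%
                 filter_features(feature_count_table(at_127, sheet), uo))

  at_128 <- base
  at_128["t1:morf", mrna_cols] <- 32
  at_128["t1_u1", rpf_cols] <- 2
  kept <- filter_features(feature_count_table(at_128, sheet), uo)
  expect_true("t1:morf" %in% kept)
  expect_true("t1_u1" %in% kept)  # exactly 8 RPF reads, 128 mRNA

  at_7 <- at_128
  at_7["t1_u1", rpf_cols] <- c(2, 2, 2, 1)
  expect_false("t1_u1" %in%
                 filter_features(feature_count_table(at_7, sheet), uo))

  expect_equal(length(filter_features(feature_count_table(base, sheet),
                                      uo)), 0)
})

test_that("differential_te recovers null and exact two-fold features", {
  tx <- transcript_models(data.frame(
    transcript_id = c("n1", "n2", "f1"), utr5_start = 0L, utr5_end = 30L,
    morf_start = 30L, morf_end = 330L, utr3_start = 330L,
    utr3_end = 400L))
  sheet <- two_by_two_sheet()
  ids <- c(paste0(rep(c("n1", "n2", "f1"), each = 3), ":",
                  c("utr5", "morf", "utr3")))
  counts <- matrix(0, nrow = length(ids), ncol = 8,
                   dimnames = list(ids, sheet$sample_id))
  counts[c("n1:morf", "n2:morf", "f1:morf"), ] <- 1000
  rpf_mut <- sheet$sample_id[sheet$assay == "RPF" &
                               sheet$genotype == "MUT"]
  counts["f1:morf", rpf_mut] <- 2000
  fct <- feature_count_table(counts, sheet)
  sf <- stats::setNames(rep(1, 8), sheet$sample_id)
  res <- differential_te(fct, sf = sf)

  null_rows <- res[res$feature_id %in% c("n1:morf", "n2:morf"), ]
  expect_equal(null_rows$log2_dte, c(0, 0))
  expect_true(all(null_rows$pvalue > 0.5))

  fold <- res[res$feature_id == "f1:morf", ]
  expect_equal(fold$log2_dte, 1.0, tolerance = 0.1)
})

test_that("classify_dependence applies fold and FDR cutoffs", {
  expect_equal(classify_dependence(-1.2, 0.001, 1.5, 0.05), "HYPER")
  expect_equal(classify_dependence(-1.2, 0.2, 1.5, 0.05), "UNCHANGED")
  expect_equal(classify_dependence(-0.9, 0.001, 2.0, 0.01), "UNCHANGED")
  expect_equal(classify_dependence(1.1, 0.001, 2.0, 0.01), "HYPO")
  expect_equal(classify_dependence(NA_real_, 0.1), NA_character_)
})

test_that("compute_crd is the cumulative half-count position", {
  expect_equal(compute_crd(track_at(rep(7, 10), 20)), 7)
  expect_equal(compute_crd(track_at(0:9, 10)), 4)
  expect_equal(compute_crd(track_at(c(2, 8), 10)), 2)
  expect_true(is.na(compute_crd(integer(10))))

  # brute-force cumulative scan oracle on random tracks
  set.seed(23)
  for (i in 1:25) {
    tr <- track_at(sample(0:49, sample(1:80, 1), replace = TRUE), 50)
    tot <- sum(tr)
    scan <- 0
    for (p in seq_along(tr)) {
      scan <- scan + tr[p]
      if (scan >= tot / 2) break
    }
    expect_equal(compute_crd(tr), p - 1)
  }
})

test_that("delta_crd averages replicates and normalizes to length", {
  expect_equal(delta_crd(c(50, 50), c(50, 50), 100), 0)
  expect_equal(delta_crd(c(60, 70), c(50, 50), 100), 0.15)
  expect_equal(delta_crd(40, 50, 100), -0.10)
  expect_equal(delta_crd(40, 50, 100, normalize = FALSE), -10)
  expect_true(is.na(delta_crd(c(40, NA), 50, 100)))
})

test_that("metagene_profile normalizes per transcript and finds peaks", {
  tx <- transcript_models(data.frame(
    transcript_id = c("m1", "m2"), utr5_start = 0L, utr5_end = 30L,
    morf_start = 30L, morf_end = 330L, utr3_start = 330L,
    utr3_end = 400L))
  uniform <- list(m1 = rep(2L, 400), m2 = rep(5L, 400))
  prof <- metagene_profile(uniform, tx, window = c(-10, 20))
  expect_equal(prof$density, rep(1, 31))

  spiked <- lapply(uniform, function(v) {
    v[31] <- v[31] * 30  # 0-based position 30 = mORF start
    v
  })
  prof2 <- metagene_profile(spiked, tx, window = c(-10, 20))
  expect_gt(prof2$density[prof2$position == 0],
            mean(prof2$density[prof2$position != 0]))

  single <- metagene_profile(uniform["m1"], tx, window = c(-10, 20))
  expect_equal(single$density, rep(1, 31))
  expect_error(metagene_profile(list(m1 = integer(400)), tx,
                                window = c(-10, 20)), "qualifies")
})

test_that("planted correlated uORF/mORF TE changes are recovered", {
  ann <- generate_annotation(n_transcripts = 800, seed = 12,
                             uorf_fraction = 0.8)
  cfg <- ribo_sim_config(mean_morf_mrna = 2000, mean_morf_rpf = 2000,
                         mean_uorf_rpf = 2000, dispersion = 0.01,
                         abund_sdlog = 0,
                         effects = list(mode = "correlated", sd_morf = 1,
                                        sd_uorf = 1, rho = 0.5))
  sim <- simulate_riboseq(ann, cfg, seed = 13)
  res <- differential_te(sim$counts, ann$uorfs)
  mres <- res[res$kind == "morf", ]
  ures <- res[res$kind == "uorf", ]
  ti <- sub(":morf", "", mres$feature_id)
  host <- ann$uorfs$transcript_id[match(ures$feature_id,
                                        ann$uorfs$uorf_id)]
  dte_m <- mres$log2_dte[match(host, ti)]
  ok <- stats::complete.cases(ures$log2_dte, dte_m)
  expect_gt(sum(ok), 500)
  sp <- spearman_rho(ures$log2_dte[ok], dte_m[ok])
  expect_gt(sp$rho, 0)
  expect_lt(abs(sp$rho - 0.5), 0.1)
})
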