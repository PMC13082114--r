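# Shared toy fixtures, built in code.

toy_transcripts <- function() {
  transcript_models(data.frame(
    transcript_id = "t1", utr5_start = 0L, utr5_end = 30L,
    morf_start = 30L, morf_end = 330L, utr3_start = 330L,
    utr3_end = 400L))
}

toy_uorfs <- function() {
  uorf_compilation(data.frame(
    uorf_id = "t1_u1", transcript_id = "t1", start = 5L, end = 14L,
    start_class = "AUG", sources = "toy"))
}

# a track with P-sites at the given 0-based positions
track_at <- function(positions, length) {
  tabulate(positions + 1L, nbins = length)
}

write_features_bed <- function(rows, path = tempfile(fileext = ".bed")) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

# random small uORF compilation over transcripts t1..t3 (spans on a grid so
# collisions between independent draws are common)
random_compilation <- function(n, tag) {
  starts <- sample(seq(0, 18, by = 3), n, replace = TRUE)
  lens <- sample(c(6L, 9L), n, replace = TRUE)
  tid <- sample(paste0("t", 1:3), n, replace = TRUE)
  df <- data.frame(tid = tid, start = starts, end = starts + lens)
  df <- unique(df)
  uorf_compilation(data.frame(
    uorf_id = paste0(tag, "_", seq_len(nrow(df))),
    transcript_id = df$tid, start = df$start, end = df$end,
    start_class = "NCC", sources = tag), provenance = tag)
}

# two-genotype, two-replicate sample sheet with both assays
two_by_two_sheet <- function() {
  sample_sheet(
    sample_id = c("RPF_WT_1", "RPF_WT_2", "RPF_MUT_1", "RPF_MUT_2",
                  "MRNA_WT_1", "MRNA_WT_2", "MRNA_MUT_1", "MRNA_MUT_2"),
    genotype = rep(rep(c("WT", "MUT"), each = 2), 2),
    assay = rep(c("RPF", "MRNA"), each = 4),
    replicate = rep(1:2, 4))
}

# exhaustive-permutation two-sided Mann-Whitney p-value (no ties)
enumerate_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  obs <- sum(rank(pooled)[seq_len(k)])
  combs <- utils::combn(n, k)
  stats <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]))
  mu <- k * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
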