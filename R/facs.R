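# FACS-uORF MPRA quantification.
#
# Reporters carry either the native uORF (variant "WT") or an AAG
# substitution of its start codon (variant "MUT"); yeast pools are sorted
# into 8 bins of increasing YFP/mCherry fluorescence and each bin is
# sequenced. The long bin-count table has one row per
# (strain, replicate, reporter) with columns bin1..bin8.

bin_cols <- paste0("bin", 1:8)

#' Mean-bin reporter expression from sort-bin counts
#'
#' Weighted mean of the bin values with weights equal to read fractions.
#' Bin values default to the bin indices 1..8; fluorescence-valued bin
#' midpoints can be supplied instead to put the estimate on the
#' fluorescence scale.
#'
#' @param counts 8-vector of bin read counts.
#' @param bin_values 8 strictly increasing bin values.
#' @param min_reads minimum total reads (default 20); below it `NA` is
#'   returned with attribute `reason`.
#' @export
estimate_reporter_expression <- function(counts, bin_values = 1:8,
                                         min_reads = 20) {
  if (length(counts) != 8 || length(bin_values) != 8)
    stop("need 8 bins")
  if (any(diff(bin_values) <= 0)) stop("bin_values must be increasing")
  tot <- sum(counts)
  if (tot < min_reads)
    return(structure(NA_real_, reason = "below min_reads"))
  sum(bin_values * counts) / tot
}

#' Wilcoxon rank-sum comparison of paired WT/Mut reporter bin counts
#'
#' The two sorted read populations are compared as if each read were an
#' observation at its bin value: the tie-corrected normal approximation
#' with continuity correction is computed directly from the bin counts
#' (every read in a bin is a tie). `direction` is `"mut_higher"` when the
#' start-codon mutant reporter fluoresces higher (a repressive uORF),
#' `"wt_higher"` for the reverse, `"none"` when degenerate. Totals above
#' `read_cap` are proportionally downsampled first.
#'
#' @param wt_counts,mut_counts 8-vectors of bin read counts for the native
#'   (WT_uORF) and start-codon-mutant (Mut_uORF) reporters.
#' @param bin_values 8 increasing bin values.
#' @param min_reads minimum reads per reporter.
#' @param read_cap per-reporter read cap (default 10000).
#' @return list with `p`, `direction`, `z`.
#' @export
wrt_compare <- function(wt_counts, mut_counts, bin_values = 1:8,
                        min_reads = 20, read_cap = 10000) {
  if (length(wt_counts) != 8 || length(mut_counts) != 8)
    stop("need 8 bins")
  cap <- function(x) {
    n <- sum(x)
    if (n > read_cap) round(x * read_cap / n) else x
  }
  if (sum(wt_counts) < min_reads || sum(mut_counts) < min_reads)
    return(list(p = NA_real_, direction = "none", z = NA_real_))
  w <- cap(wt_counts)
  m <- cap(mut_counts)
  n1 <- sum(m)
  n2 <- sum(w)
  N <- n1 + n2
  t_b <- w + m
  cum <- cumsum(t_b)
  midrank <- cum - t_b / 2 + 0.5
  W1 <- sum(m * midrank)
  U1 <- W1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_term <- sum(t_b^3 - t_b) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  mean_m <- sum(m * bin_values) / n1
  mean_w <- sum(w * bin_values) / n2
  if (v <= 0) {
    return(list(p = 1, direction = "none", z = 0))
  }
  z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(v)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  direction <- if (mean_m > mean_w) "mut_higher"
  else if (mean_m < mean_w) "wt_higher" else "none"
  list(p = p, direction = direction, z = z)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH q-values in input order, clipped at 1.
#' @param pvalues numeric vector in `[0, 1]` (NA allowed).
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call a consistent significant regulator (CSR) uORF
#'
#' A uORF is a CSR when every replicate with data is significant
#' (q < `alpha`) with the same non-degenerate direction, and at least
#' `min_replicates` replicates have data.
#'
#' @param q per-replicate BH-adjusted p-values.
#' @param directions per-replicate directions (`"mut_higher"`,
#'   `"wt_higher"`, `"none"`).
#' @param alpha per-replicate FDR threshold (default 0.05).
#' @param min_replicates minimum informative replicates (default 2).
#' @return list with `csr` (logical), `direction` (`"repressive"` when
#'   the mutant reporter runs higher, `"enhancing"` for the reverse,
#'   `"none"`), and `n_informative`.
#' @export
call_csr <- function(q, directions, alpha = 0.05, min_replicates = 2) {
  ok <- !is.na(q)
  n_inf <- sum(ok)
  if (n_inf < min_replicates)
    return(list(csr = FALSE, direction = "none", n_informative = n_inf))
  qs <- q[ok]
  ds <- directions[ok]
  csr <- all(qs < alpha) && length(unique(ds)) == 1 && ds[1] != "none"
  dir <- if (!csr) "none"
  else if (ds[1] == "mut_higher") "repressive" else "enhancing"
  list(csr = csr, direction = dir, n_informative = n_inf)
}

#' uORF effect: expression with the uORF over expression without it
#'
#' Values below 1 indicate repression by the uORF.
#' @param expr_with expression of the native (+uORF) reporter.
#' @param expr_without expression of the start-codon-mutant (-uORF)
#'   reporter.
#' @export
uorf_effect <- function(expr_with, expr_without) {
  ifelse(is.na(expr_with) | is.na(expr_without) |
           expr_with <= 0 | expr_without <= 0,
         NA_real_, expr_with / expr_without)
}

#' Cross-strain ratio of uORF effects and Ded1-modulation class
#'
#' The ratio of the mutant-strain uORF effect to the wild-type-strain
#' effect. Ratios below 1/fold indicate the uORF is more inhibitory when
#' Ded1 is impaired (`ded1_suppressed`, the Ded1-START expectation);
#' ratios above fold are `ded1_enhanced`; otherwise `neutral`.
#'
#' @param effect_mut_strain,effect_wt_strain strain-specific uORF effects.
#' @param fold_threshold modulation fold cutoff (default 1.33).
#' @return list with `ratio` and `modulation`.
#' @export
effect_ratio <- function(effect_mut_strain, effect_wt_strain,
                         fold_threshold = 1.33) {
  if (is.na(effect_mut_strain) || is.na(effect_wt_strain) ||
      effect_mut_strain <= 0 || effect_wt_strain <= 0)
    return(list(ratio = NA_real_, modulation = NA_character_))
  r <- effect_mut_strain / effect_wt_strain
  mod <- if (r < 1 / fold_threshold) "ded1_suppressed"
  else if (r > fold_threshold) "ded1_enhanced" else "neutral"
  list(ratio = r, modulation = mod)
}

#' Full FACS-uORF library analysis
#'
#' Per uORF and strain: per-replicate WT-vs-Mut rank-sum tests, BH
#' adjustment across uORFs within each (strain, replicate), CSR calls,
#' replicate-pooled expression estimates, uORF effects, and the
#' cross-strain effect ratio with its modulation class. Inference is
#' per-replicate; point estimates pool read counts across replicates.
#'
#' @param bins long data.frame with columns `strain`, `replicate`, `gene`,
#'   `uorf_id`, `variant` (`WT`/`MUT`) and `bin1`..`bin8`; exactly two
#'   strains, the first level (or `wt_strain`) being the wild-type strain.
#' @param bin_values 8 increasing bin values shared by all strains, or a
#'   named list of per-strain values (e.g. fluorescence midpoints).
#' @param wt_strain name of the wild-type strain (default: first of the
#'   sorted unique strains).
#' @param fdr per-replicate CSR threshold (default 0.05).
#' @param fold_threshold modulation cutoff for effect ratios.
#' @param min_reads,read_cap see [estimate_reporter_expression] and
#'   [wrt_compare].
#' @return list (`facs_summary`): `table` (per-uORF data.frame),
#'   `cohort` (summary statistics over the CSR-in-either-strain subset
#'   with complete data), `unpaired` (count of reporters lacking a
#'   partner).
#' @export
summarize_library <- function(bins, bin_values = 1:8, wt_strain = NULL,
                              fdr = 0.05, fold_threshold = 1.33,
                              min_reads = 20, read_cap = 10000) {
  strains <- sort(unique(bins$strain))
  if (length(strains) != 2) stop("need exactly two strains")
  if (is.null(wt_strain)) wt_strain <- strains[1]
  mut_strain <- setdiff(strains, wt_strain)
  vals_for <- function(s) {
    if (is.list(bin_values)) bin_values[[s]] else bin_values
  }
  reps <- sort(unique(bins$replicate))
  uorfs <- unique(bins[c("gene", "uorf_id")])
  uorfs <- uorfs[order(uorfs$uorf_id), , drop = FALSE]

  # drop uORFs without both variants in both strains' pooled data
  have <- table(bins$uorf_id, bins$variant)
  paired <- rownames(have)[have[, "WT"] > 0 & have[, "MUT"] > 0]
  unpaired <- sum(!uorfs$uorf_id %in% paired)
  uorfs <- uorfs[uorfs$uorf_id %in% paired, , drop = FALSE]
  n <- nrow(uorfs)

  binmat <- as.matrix(bins[bin_cols])
  idx_rep <- split(seq_len(nrow(bins)),
                   paste(bins$strain, bins$replicate, bins$uorf_id,
                         bins$variant, sep = "\r"))
  idx_pool <- split(seq_len(nrow(bins)),
                    paste(bins$strain, bins$uorf_id, bins$variant,
                          sep = "\r"))
  get_counts <- function(s, r, u, v) {
    ix <- idx_rep[[paste(s, r, u, v, sep = "\r")]]
    if (is.null(ix)) return(NULL)
    colSums(binmat[ix, , drop = FALSE])
  }
  get_pooled <- function(s, u, v) {
    ix <- idx_pool[[paste(s, u, v, sep = "\r")]]
    if (is.null(ix)) return(NULL)
    colSums(binmat[ix, , drop = FALSE])
  }

  per_strain <- list()
  for (s in strains) {
    bv <- vals_for(s)
    pmat <- matrix(NA_real_, n, length(reps))
    dmat <- matrix("none", n, length(reps))
    for (j in seq_along(reps)) {
      for (i in seq_len(n)) {
        w <- get_counts(s, reps[j], uorfs$uorf_id[i], "WT")
        m <- get_counts(s, reps[j], uorfs$uorf_id[i], "MUT")
        if (is.null(w) || is.null(m)) next
        res <- wrt_compare(w, m, bv, min_reads, read_cap)
        pmat[i, j] <- res$p
        dmat[i, j] <- res$direction
      }
      pmat[, j] <- ifelse(is.na(pmat[, j]), NA, pmat[, j])
    }
    qmat <- apply(pmat, 2, bh_adjust)
    if (is.null(dim(qmat))) qmat <- matrix(qmat, nrow = n)
    csr <- vector("logical", n)
    cdir <- character(n)
    for (i in seq_len(n)) {
      cc <- call_csr(qmat[i, ], dmat[i, ], alpha = fdr)
      csr[i] <- cc$csr
      cdir[i] <- cc$direction
    }
    # replicate-pooled expression per variant
    expr <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("WT", "MUT")))
    for (v in c("WT", "MUT")) {
      expr[, v] <- vapply(seq_len(n), function(i) {
        cc <- get_pooled(s, uorfs$uorf_id[i], v)
        if (is.null(cc)) return(NA_real_)
        as.numeric(estimate_reporter_expression(cc, bv, min_reads))
      }, numeric(1))
    }
    eff <- uorf_effect(expr[, "WT"], expr[, "MUT"])
    per_strain[[s]] <- list(q = qmat, dir = dmat, csr = csr, cdir = cdir,
                            expr_with = expr[, "WT"],
                            expr_without = expr[, "MUT"], effect = eff)
  }

  wt <- per_strain[[wt_strain]]
  mu <- per_strain[[mut_strain]]
  er <- lapply(seq_len(n), function(i)
    effect_ratio(mu$effect[i], wt$effect[i], fold_threshold))
  tab <- data.frame(
    gene = uorfs$gene, uorf_id = uorfs$uorf_id,
    expr_with_wt = wt$expr_with, expr_without_wt = wt$expr_without,
    expr_with_mut = mu$expr_with, expr_without_mut = mu$expr_without,
    effect_wt_strain = wt$effect, effect_mut_strain = mu$effect,
    effect_ratio = vapply(er, function(e) e$ratio, numeric(1)),
    modulation = vapply(er, function(e)
      if (is.null(e$modulation) || is.na(e$modulation)) NA_character_
      else e$modulation, character(1)),
    csr_wt_strain = wt$csr, csr_mut_strain = mu$csr,
    csr_dir_wt_strain = wt$cdir, csr_dir_mut_strain = mu$cdir,
    row.names = NULL)

  complete <- stats::complete.cases(
    tab[c("effect_wt_strain", "effect_mut_strain", "effect_ratio")])
  either <- complete & (tab$csr_wt_strain | tab$csr_mut_strain)
  mut_only <- complete & tab$csr_mut_strain
  cohort <- list(
    n_uorfs = n,
    n_csr_wt_strain = sum(tab$csr_wt_strain),
    n_csr_mut_strain = sum(tab$csr_mut_strain),
    n_csr_either = sum(either),
    median_effect_wt_strain = stats::median(tab$effect_wt_strain,
                                            na.rm = TRUE),
    median_effect_mut_strain = stats::median(tab$effect_mut_strain,
                                             na.rm = TRUE),
    median_effect_ratio = stats::median(tab$effect_ratio, na.rm = TRUE),
    modulation_counts = table(factor(
      tab$modulation[either],
      levels = c("ded1_suppressed", "neutral", "ded1_enhanced"))),
    effects_mwu = if (sum(either) >= 1)
      mann_whitney_u(log2(tab$effect_wt_strain[either]),
                     log2(tab$effect_mut_strain[either]))
    else NULL,
    subset_either = tab$uorf_id[either],
    subset_mut_only = tab$uorf_id[mut_only])
  structure(list(table = tab, cohort = cohort, unpaired = unpaired,
                 wt_strain = wt_strain, mut_strain = mut_strain),
            class = "facs_summary")
}

#' Read a FACS bin-count table from TSV
#'
#' Columns: `strain`, `replicate`, `gene`, `uorf_id`, `variant`,
#' `bin1`..`bin8`.
#' @param path TSV path.
#' @export
read_facs_bins <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("strain", "replicate", "gene", "uorf_id", "variant", bin_cols)
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write a FACS bin-count table to TSV
#' @param bins long bin-count data.frame.
#' @param path output path.
#' @export
write_facs_bins <- function(bins, path) {
  utils::write.table(bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
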