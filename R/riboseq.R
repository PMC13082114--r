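# Feature-level Ribo-Seq quantification: P-site assignment, feature counting
# with exclusion rules, size factors, relative TE, differential TE via a
# negative-binomial interaction test, CRD/deltaCRD and metagene profiles.
#
# A "track" is an integer vector of P-site (or mRNA fragment) counts per
# nucleotide of one transcript; a track set is a named list
# sample_id -> (named list transcript_id -> track).

#' Build a sample sheet
#'
#' @param sample_id unique sample identifiers.
#' @param genotype `"WT"` or `"MUT"` per sample.
#' @param assay `"RPF"` or `"MRNA"` per sample.
#' @param replicate integer replicate index (>= 1) per sample.
#' @export
sample_sheet <- function(sample_id, genotype, assay, replicate) {
  df <- data.frame(sample_id = sample_id, genotype = genotype,
                   assay = assay, replicate = as.integer(replicate))
  if (!all(df$genotype %in% c("WT", "MUT"))) stop("genotype must be WT/MUT")
  if (!all(df$assay %in% c("RPF", "MRNA"))) stop("assay must be RPF/MRNA")
  if (anyDuplicated(df[c("genotype", "assay", "replicate")]))
    stop("(genotype, assay, replicate) must be unique")
  if (anyDuplicated(df$sample_id)) stop("sample_id must be unique")
  df
}

#' Assign P-sites to footprint 5' ends
#'
#' P-site position = 5' end + length-specific offset. Reads whose P-site
#' falls outside the transcript are dropped and tallied.
#'
#' @param positions integer vector of 0-based 5'-end positions.
#' @param lengths integer vector of read lengths (same length as
#'   `positions`).
#' @param transcript_length transcript length in nt.
#' @param offsets named numeric vector mapping read length to offset;
#'   the default applies 12 nt to the 25-34 nt size-selection range.
#' @param default_offset fallback for unlisted lengths (`NA` = error).
#' @return integer track of length `transcript_length` with attribute
#'   `dropped` (number of out-of-bounds P-sites).
#' @export
assign_psites <- function(positions, lengths, transcript_length,
                          offsets = stats::setNames(rep(12L, 10L), 25:34),
                          default_offset = NA) {
  off <- offsets[as.character(lengths)]
  if (anyNA(off)) {
    if (is.na(default_offset))
      stop("no offset for read length(s): ",
           paste(sort(unique(lengths[is.na(off)])), collapse = ", "),
           " (supply default_offset)")
    off[is.na(off)] <- default_offset
  }
  p <- positions + as.integer(off)
  ok <- p >= 0 & p < transcript_length
  track <- tabulate(p[ok] + 1L, nbins = transcript_length)
  attr(track, "dropped") <- sum(!ok)
  track
}

feature_ids_for <- function(transcripts, uorfs = NULL) {
  c(paste0(rep(transcripts$transcript_id, each = 3),
           ":", c("utr5", "morf", "utr3")),
    if (!is.null(uorfs)) uorfs$uorf_id)
}

span_sum <- function(track, start, end) {
  if (is.null(track) || end <= start) return(0)
  sum(track[(start + 1):end])
}

#' Count reads per annotated feature for one sample
#'
#' For footprint tracks (`exclude = TRUE`) the first and last nucleotide
#' triplets of each 5'UTR and the first 20 codons (60 nt) of each mORF are
#' excluded from their feature counts; uORF and 3'UTR counts use full
#' spans. mRNA tracks are counted over full spans (`exclude = FALSE`).
#'
#' @param tracks named list transcript_id -> integer track.
#' @param transcripts `transcript_models`.
#' @param uorfs optional `uorf_compilation`.
#' @param exclude apply the footprint exclusion zones.
#' @return named numeric vector over features
#'   (`<tid>:utr5|morf|utr3` and uORF ids) with attributes `excluded`
#'   (reads falling in exclusion zones, per transcript) and `flags`
#'   (features zeroed because the span is shorter than the exclusions).
#' @export
count_features <- function(tracks, transcripts, uorfs = NULL,
                           exclude = TRUE) {
  ids <- feature_ids_for(transcripts, uorfs)
  out <- stats::setNames(numeric(length(ids)), ids)
  excluded <- stats::setNames(numeric(nrow(transcripts)),
                              transcripts$transcript_id)
  flags <- character()
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    tr <- tracks[[t$transcript_id]]
    full5 <- span_sum(tr, t$utr5_start, t$utr5_end)
    fullm <- span_sum(tr, t$morf_start, t$morf_end)
    if (exclude) {
      if (t$utr5_end - t$utr5_start < 6) {
        c5 <- 0
        flags <- c(flags, paste0(t$transcript_id, ":utr5"))
      } else {
        c5 <- span_sum(tr, t$utr5_start + 3, t$utr5_end - 3)
      }
      if (t$morf_end - t$morf_start <= 60) {
        cm <- 0
        flags <- c(flags, paste0(t$transcript_id, ":morf"))
      } else {
        cm <- span_sum(tr, t$morf_start + 60, t$morf_end)
      }
      excluded[t$transcript_id] <- (full5 - c5) + (fullm - cm)
    } else {
      c5 <- full5
      cm <- fullm
    }
    out[paste0(t$transcript_id, ":utr5")] <- c5
    out[paste0(t$transcript_id, ":morf")] <- cm
    out[paste0(t$transcript_id, ":utr3")] <-
      span_sum(tr, t$utr3_start, t$utr3_end)
  }
  if (!is.null(uorfs)) {
    for (i in seq_len(nrow(uorfs))) {
      u <- uorfs[i, ]
      out[u$uorf_id] <- span_sum(tracks[[u$transcript_id]], u$start, u$end)
    }
  }
  attr(out, "excluded") <- excluded
  attr(out, "flags") <- flags
  out
}

#' Assemble a feature x sample count table from track sets
#'
#' Exclusion zones are applied to RPF samples only.
#'
#' @param track_sets named list sample_id -> track list.
#' @param samples sample sheet (see [sample_sheet]).
#' @param transcripts `transcript_models`.
#' @param uorfs optional `uorf_compilation`.
#' @return a `feature_counts` object: list with integer matrix `counts`
#'   (features x samples) and the `samples` sheet.
#' @export
build_count_table <- function(track_sets, samples, transcripts,
                              uorfs = NULL) {
  cols <- lapply(samples$sample_id, function(s) {
    count_features(track_sets[[s]], transcripts, uorfs,
                   exclude = samples$assay[samples$sample_id == s] == "RPF")
  })
  counts <- do.call(cbind, cols)
  colnames(counts) <- samples$sample_id
  feature_count_table(counts, samples)
}

#' Construct a feature count table from a matrix
#'
#' @param counts integer matrix, features x samples; rownames are feature
#'   ids (`<tid>:utr5|morf|utr3` or uORF ids), colnames are sample ids.
#' @param samples sample sheet.
#' @export
feature_count_table <- function(counts, samples) {
  if (is.null(rownames(counts))) stop("counts needs feature rownames")
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(counts = counts, samples = samples),
            class = "feature_counts")
}

feature_kind <- function(ids) {
  kind <- rep("uorf", length(ids))
  kind[grepl(":utr5$", ids)] <- "utr5"
  kind[grepl(":morf$", ids)] <- "morf"
  kind[grepl(":utr3$", ids)] <- "utr3"
  kind
}

host_morf <- function(ids, uorfs) {
  kind <- feature_kind(ids)
  host <- sub(":(utr5|morf|utr3)$", "", ids)
  if (any(kind == "uorf")) {
    map <- stats::setNames(uorfs$transcript_id, uorfs$uorf_id)
    host[kind == "uorf"] <- map[ids[kind == "uorf"]]
  }
  paste0(host, ":morf")
}

#' Median-of-ratios size factors per assay
#'
#' Computed over mORF rows with all-positive counts within each assay and
#' rescaled to geometric mean 1 within the assay; falls back to total-count
#' scaling (with a warning) when no such row exists.
#'
#' @param fct `feature_counts` object.
#' @return named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(fct) {
  counts <- fct$counts
  samples <- fct$samples
  morf <- counts[feature_kind(rownames(counts)) == "morf", , drop = FALSE]
  sf <- stats::setNames(numeric(nrow(samples)), samples$sample_id)
  for (a in unique(samples$assay)) {
    ids <- samples$sample_id[samples$assay == a]
    sub <- morf[, ids, drop = FALSE]
    pos <- rowSums(sub > 0) == ncol(sub)
    if (!any(pos)) {
      warning("no all-positive mORF row for assay ", a,
              "; using total-count scaling")
      raw <- colSums(sub)
      if (any(raw == 0)) raw[] <- 1
    } else {
      sub <- sub[pos, , drop = FALSE]
      geo <- exp(rowMeans(log(sub)))
      raw <- apply(sub / geo, 2, stats::median)
    }
    sf[ids] <- raw / exp(mean(log(raw)))
  }
  sf
}

#' Retain features passing the read-count thresholds
#'
#' mORF features are retained iff the summed mRNA reads of the host mORF
#' over all samples reach `min_morf_mrna` (default 128 over the 4 samples
#' of a two-genotype, two-replicate comparison); uORF and 5'UTR features
#' additionally require `min_uorf_rpf` (default 8) summed RPF reads.
#'
#' @param fct `feature_counts` object.
#' @param uorfs `uorf_compilation` (maps uORFs to host transcripts).
#' @param min_morf_mrna,min_uorf_rpf inclusion thresholds.
#' @return character vector of retained feature ids.
#' @export
filter_features <- function(fct, uorfs = NULL, min_morf_mrna = 128,
                            min_uorf_rpf = 8) {
  counts <- fct$counts
  samples <- fct$samples
  ids <- rownames(counts)
  kind <- feature_kind(ids)
  mrna_tot <- rowSums(counts[, samples$sample_id[samples$assay == "MRNA"],
                             drop = FALSE])
  rpf_tot <- rowSums(counts[, samples$sample_id[samples$assay == "RPF"],
                            drop = FALSE])
  host <- host_morf(ids, uorfs)
  host_mrna <- mrna_tot[host]
  keep <- !is.na(host_mrna) & host_mrna >= min_morf_mrna &
    kind != "utr3" &
    (kind == "morf" | rpf_tot >= min_uorf_rpf)
  ids[keep]
}

#' Relative translational efficiencies per genotype
#'
#' TE of a 5'UTR or uORF feature is its normalized RPF count divided by
#' the normalized mRNA count of the host transcript's mORF; mORF TE is
#' mORF RPF over mORF mRNA. Per replicate, a pseudocount is added to
#' numerator and denominator; the genotype value is the geometric mean of
#' the per-replicate ratios.
#'
#' @param fct `feature_counts` object.
#' @param uorfs `uorf_compilation`.
#' @param sf size factors (default [size_factors]).
#' @param pseudocount added to numerator and denominator (default 0.5;
#'   0 disables, in which case zero denominators give `NA`).
#' @return data.frame with `feature_id`, `kind`, `te_wt`, `te_mut`,
#'   `log2_te_ratio`.
#' @export
compute_te <- function(fct, uorfs = NULL, sf = size_factors(fct),
                       pseudocount = 0.5) {
  counts <- fct$counts
  samples <- fct$samples
  norm <- sweep(counts, 2, sf[colnames(counts)], "/")
  ids <- rownames(counts)
  host <- host_morf(ids, uorfs)
  te_for <- function(geno) {
    reps <- sort(unique(samples$replicate[samples$genotype == geno]))
    ratios <- sapply(reps, function(r) {
      rpf_s <- samples$sample_id[samples$genotype == geno &
                                   samples$assay == "RPF" &
                                   samples$replicate == r]
      mrna_s <- samples$sample_id[samples$genotype == geno &
                                    samples$assay == "MRNA" &
                                    samples$replicate == r]
      if (!length(rpf_s) || !length(mrna_s)) return(rep(NA_real_,
                                                        length(ids)))
      num <- norm[ids, rpf_s] + pseudocount
      den <- norm[host, mrna_s] + pseudocount
      ifelse(den > 0, num / den, NA_real_)
    })
    exp(rowMeans(log(ratios)))
  }
  te_wt <- te_for("WT")
  te_mut <- te_for("MUT")
  data.frame(feature_id = ids, kind = feature_kind(ids),
             te_wt = te_wt, te_mut = te_mut,
             log2_te_ratio = log2(te_mut / te_wt), row.names = NULL)
}

#' Differential TE via a negative-binomial interaction test
#'
#' Per feature, raw RPF counts of the feature and raw mRNA counts of the
#' host mORF are modelled jointly with a negative-binomial GLM,
#' `count ~ assay * genotype` with log size-factor offsets. The
#' assay:genotype interaction is the log fold-change of TE in the mutant;
#' it is reported on the log2 scale with a Wald test. Per-feature
#' dispersions are method-of-moments estimates shrunk halfway toward a
#' 1/mean trend fitted across all tested features, and the Wald statistic
#' is referred to a t distribution whose degrees of freedom are the
#' residual df plus an equal number of prior df contributed by the trend.
#' BH adjustment is applied within families (mORFs separately from
#' uORF/5'UTR features). Features failing [filter_features] are reported
#' as `FILTERED`.
#'
#' @param fct `feature_counts` object.
#' @param uorfs `uorf_compilation`.
#' @param sf size factors (default [size_factors]).
#' @param min_morf_mrna,min_uorf_rpf filter thresholds (see
#'   [filter_features]).
#' @param morf_thresholds,uorf_thresholds `c(fold, fdr)` used by
#'   [classify_dependence] for the two families.
#' @return data.frame (`te_results`): `feature_id`, `kind`, `base_mean`,
#'   `te_wt`, `te_mut`, `log2_dte`, `se`, `pvalue`, `fdr`, `class`,
#'   `converged`.
#' @export
differential_te <- function(fct, uorfs = NULL, sf = size_factors(fct),
                            min_morf_mrna = 128, min_uorf_rpf = 8,
                            morf_thresholds = c(1.5, 0.05),
                            uorf_thresholds = c(2.0, 0.01)) {
  counts <- fct$counts
  samples <- fct$samples
  if (min(table(samples$assay, samples$genotype)) < 2)
    stop("need >= 2 replicates per genotype per assay")
  ids <- rownames(counts)
  kind <- feature_kind(ids)
  host <- host_morf(ids, uorfs)
  retained <- filter_features(fct, uorfs, min_morf_mrna, min_uorf_rpf)
  tested <- ids[ids %in% retained & kind %in% c("morf", "uorf", "utr5")]

  ord <- order(samples$assay, samples$genotype, samples$replicate)
  sam <- samples[ord, ]
  assay <- factor(sam$assay, levels = c("MRNA", "RPF"))
  geno <- factor(sam$genotype, levels = c("WT", "MUT"))
  X <- stats::model.matrix(~ assay * geno)
  off <- log(sf[sam$sample_id])
  cell <- interaction(assay, geno)
  n_cells <- nlevels(droplevels(cell))
  resid_df <- nrow(sam) - ncol(X)

  # per-feature response: RPF counts of the feature, mRNA counts of host mORF
  ymat <- t(vapply(tested, function(f) {
    y <- numeric(nrow(sam))
    is_rpf <- sam$assay == "RPF"
    y[is_rpf] <- counts[f, sam$sample_id[is_rpf]]
    y[!is_rpf] <- counts[host[ids == f], sam$sample_id[!is_rpf]]
    y
  }, numeric(nrow(sam))))

  # method-of-moments dispersion on size-factor-normalized counts
  normy <- sweep(ymat, 2, exp(off), "/")
  mu_i <- rowMeans(normy)
  mom <- apply(normy, 1, function(y) {
    ms <- tapply(y, cell, mean)
    vs <- tapply(y, cell, stats::var)
    s <- sum(ms^2)
    if (s == 0) return(NA_real_)
    sum(vs - ms) / s
  })
  ok_tr <- !is.na(mom) & mom > 0 & mu_i > 0
  if (sum(ok_tr) >= 10) {
    cf <- stats::coef(stats::lm(mom[ok_tr] ~ I(1 / mu_i[ok_tr])))
    trend <- pmax(1e-8, cf[1] + cf[2] / pmax(mu_i, 1e-8))
  } else {
    trend <- rep(max(1e-8, stats::median(mom[ok_tr], na.rm = TRUE),
                     na.rm = TRUE), length(mu_i))
  }
  alpha <- 0.5 * pmax(ifelse(is.na(mom), 0, mom), 0) + 0.5 * trend

  fit_one <- function(y, a) {
    fam <- MASS::negative.binomial(theta = 1 / a)
    f <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) return(c(NA, NA, FALSE))
    w <- f$weights
    info <- crossprod(X * sqrt(w))
    se <- tryCatch(sqrt(solve(info)[4, 4]), error = function(e) NA_real_)
    c(f$coefficients[4], se, TRUE)
  }
  est <- t(vapply(seq_along(tested),
                  function(i) fit_one(ymat[i, ], alpha[i]), numeric(3)))
  b <- est[, 1]
  se <- est[, 2]
  conv <- est[, 3] == 1 & !is.na(se) & se > 0
  tstat <- ifelse(conv, b / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tstat), df = 2 * resid_df)

  te <- compute_te(fct, uorfs, sf)
  res <- data.frame(feature_id = ids, kind = kind, row.names = NULL)
  res$base_mean <- NA_real_
  res$base_mean[match(tested, ids)] <- mu_i
  res$te_wt <- te$te_wt
  res$te_mut <- te$te_mut
  res$log2_dte <- NA_real_
  res$log2_dte[match(tested, ids)] <- b / log(2)
  res$se <- NA_real_
  res$se[match(tested, ids)] <- se / log(2)
  res$pvalue <- NA_real_
  res$pvalue[match(tested, ids)] <- pval
  res$converged <- NA
  res$converged[match(tested, ids)] <- conv
  res$fdr <- NA_real_
  fam_morf <- res$feature_id %in% tested & res$kind == "morf"
  fam_uorf <- res$feature_id %in% tested & res$kind %in% c("uorf", "utr5")
  res$fdr[fam_morf] <- stats::p.adjust(res$pvalue[fam_morf], method = "BH")
  res$fdr[fam_uorf] <- stats::p.adjust(res$pvalue[fam_uorf], method = "BH")
  res$class <- "FILTERED"
  res$class[fam_morf] <- classify_dependence(
    res$log2_dte[fam_morf], res$fdr[fam_morf],
    morf_thresholds[1], morf_thresholds[2])
  res$class[fam_uorf] <- classify_dependence(
    res$log2_dte[fam_uorf], res$fdr[fam_uorf],
    uorf_thresholds[1], uorf_thresholds[2])
  res[res$kind != "utr3", , drop = FALSE]
}

#' Classify Ded1 dependence from differential-TE estimates
#'
#' `HYPER` (hyperdependent: TE down in the mutant) when
#' log2 dTE <= -log2(fold) at FDR below the cutoff, `HYPO` for the
#' mirror-image increase, otherwise `UNCHANGED`.
#'
#' @param log2_dte,fdr numeric vectors.
#' @param fold_threshold fold-change cutoff (1.5 for mORFs, 2 for uORFs by
#'   convention).
#' @param fdr_threshold FDR cutoff (0.05 for mORFs, 0.01 for uORFs).
#' @export
classify_dependence <- function(log2_dte, fdr, fold_threshold = 1.5,
                                fdr_threshold = 0.05) {
  lf <- log2(fold_threshold)
  out <- rep("UNCHANGED", length(log2_dte))
  sig <- !is.na(log2_dte) & !is.na(fdr) & fdr < fdr_threshold
  out[sig & log2_dte <= -lf] <- "HYPER"
  out[sig & log2_dte >= lf] <- "HYPO"
  out[is.na(log2_dte)] <- NA_character_
  out
}

#' Center of ribosome density
#'
#' Smallest 0-based position whose cumulative footprint count reaches half
#' the transcript total.
#'
#' @param track integer track.
#' @return 0-based position, or `NA` for an empty track.
#' @export
compute_crd <- function(track) {
  tot <- sum(track)
  if (tot == 0) return(NA_real_)
  which(cumsum(track) >= tot / 2)[1] - 1
}

#' Between-genotype CRD shift
#'
#' Mean mutant CRD minus mean wild-type CRD, normalized to transcript
#' length by default. Negative values indicate a 5'-ward shift of ribosome
#' density in the mutant.
#'
#' @param crd_mut,crd_wt replicate CRD values per genotype.
#' @param length transcript length in nt.
#' @param normalize divide the shift by `length`.
#' @export
delta_crd <- function(crd_mut, crd_wt, length, normalize = TRUE) {
  if (anyNA(crd_mut) || anyNA(crd_wt)) return(NA_real_)
  d <- mean(crd_mut) - mean(crd_wt)
  if (normalize) d / length else d
}

#' Per-transcript CRD table from footprint track sets
#'
#' @param track_sets named list sample_id -> track list (RPF samples are
#'   selected from the sheet).
#' @param samples sample sheet.
#' @param transcripts `transcript_models`.
#' @param normalize length-normalize the shift (see [delta_crd]).
#' @return data.frame with `transcript_id`, `crd_wt`, `crd_mut`,
#'   `delta_crd`.
#' @export
crd_table <- function(track_sets, samples, transcripts, normalize = TRUE) {
  rpf <- samples[samples$assay == "RPF", ]
  out <- lapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i, ]
    crds <- vapply(rpf$sample_id, function(s) {
      tr <- track_sets[[s]][[t$transcript_id]]
      if (is.null(tr)) NA_real_ else compute_crd(tr)
    }, numeric(1))
    cw <- crds[rpf$genotype == "WT"]
    cm <- crds[rpf$genotype == "MUT"]
    data.frame(transcript_id = t$transcript_id,
               crd_wt = mean(cw), crd_mut = mean(cm),
               delta_crd = delta_crd(cm, cw, t$length, normalize))
  })
  do.call(rbind, out)
}

#' Metagene footprint profile anchored at the mORF start
#'
#' Each qualifying transcript's density over the window is scaled by its
#' own mean density in the window, and the profile is the position-wise
#' mean over transcripts. Positions are reported relative to the anchor
#' (first nucleotide of the mORF = 0).
#'
#' @param tracks named list transcript_id -> track (one sample, or tracks
#'   summed over samples).
#' @param transcripts `transcript_models`.
#' @param window `c(-upstream, +downstream)` in nt around the anchor.
#' @param min_reads minimum reads within the window for inclusion.
#' @return data.frame with `position` and mean normalized `density`.
#' @export
metagene_profile <- function(tracks, transcripts, window = c(-24, 59),
                             min_reads = 32) {
  offs <- window[1]:window[2]
  profs <- list()
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    tr <- tracks[[t$transcript_id]]
    if (is.null(tr)) next
    pos <- t$morf_start + offs
    if (pos[1] < 0 || pos[length(pos)] >= t$length) next
    v <- tr[pos + 1]
    if (sum(v) < min_reads) next
    profs[[length(profs) + 1]] <- v / mean(v)
  }
  if (!length(profs)) stop("no transcript qualifies for the metagene window")
  data.frame(position = offs,
             density = rowMeans(do.call(cbind, profs)))
}
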