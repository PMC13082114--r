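# PARS-based secondary-structure scores over 5'UTR windows.
#
# A PARS profile is a numeric vector over transcript positions (0-based
# indexing via position + 1); positions without data are NA. Higher scores
# indicate more double-stranded structure.

#' Cumulative PARS score of a fixed window downstream of a start codon
#'
#' The window is given in 1-based offsets relative to the +1 nucleotide
#' (the first nucleotide of the start codon), inclusive of both endpoints:
#' window (16, 45) covers the 30 nt at offsets 16..45. Missing values are
#' imputed as 0 and reported through the `coverage` attribute; windows with
#' coverage below `min_coverage` or extending past the transcript return
#' `NA`.
#'
#' @param profile numeric PARS vector for the transcript (NA = no data).
#' @param anchor 0-based position of the first nucleotide of the start
#'   codon.
#' @param window `c(a, b)` 1-based inclusive offsets downstream of +1.
#' @param min_coverage minimum fraction of non-missing positions.
#' @return window score with attribute `coverage`, or `NA` (attribute
#'   `reason`) when out of bounds or under-covered.
#' @export
window_score <- function(profile, anchor, window = c(16, 45),
                         min_coverage = 0.8) {
  idx <- anchor + (window[1]:window[2])  # 1-based vector index
  if (idx[1] < 1 || idx[length(idx)] > length(profile)) {
    return(structure(NA_real_, reason = "window outside transcript"))
  }
  vals <- profile[idx]
  coverage <- mean(!is.na(vals))
  if (coverage < min_coverage) {
    return(structure(NA_real_, coverage = coverage,
                     reason = "insufficient coverage"))
  }
  structure(sum(vals, na.rm = TRUE), coverage = coverage)
}

#' Maximum 30-nt sliding-window PARS score within a 5'UTR
#'
#' The maximum, over all 30-nt windows fully inside the 5'UTR, of the
#' window sum (missing values as 0). 5'UTRs shorter than 30 nt score the
#' sum over the whole UTR. Returns `NA` when no position in the UTR has
#' data.
#'
#' @param profile numeric PARS vector.
#' @param utr5 `c(start, end)` 0-based half-open 5'UTR span.
#' @param width window width in nt (default 30).
#' @export
max30 <- function(profile, utr5, width = 30) {
  idx <- (utr5[1] + 1):utr5[2]
  vals <- profile[idx]
  if (all(is.na(vals))) return(NA_real_)
  n <- length(vals)
  v0 <- ifelse(is.na(vals), 0, vals)
  if (n <= width) return(sum(v0))
  cs <- cumsum(c(0, v0))
  max(cs[(width + 1):(n + 1)] - cs[1:(n - width + 1)])
}

#' Total PARS score across a 5'UTR
#'
#' Sum over the 5'UTR with missing values as 0; the fraction of covered
#' positions is attached as `coverage`.
#'
#' @param profile numeric PARS vector.
#' @param utr5 `c(start, end)` 0-based half-open span.
#' @export
total_utr_score <- function(profile, utr5) {
  vals <- profile[(utr5[1] + 1):utr5[2]]
  structure(sum(vals, na.rm = TRUE), coverage = mean(!is.na(vals)))
}

#' Read per-nucleotide PARS scores from TSV
#'
#' Expects columns `transcript_id`, `position` (0-based) and `score`.
#' Positions absent from the file are NA.
#'
#' @param path TSV path.
#' @param transcripts `transcript_models` giving vector lengths.
#' @return named list transcript_id -> numeric profile.
#' @export
read_pars_profiles <- function(path, transcripts) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("transcript_id", "position", "score")
  if (!all(req %in% names(df)))
    stop("PARS TSV needs columns: ", paste(req, collapse = ", "))
  out <- stats::setNames(
    lapply(transcripts$length, function(L) rep(NA_real_, L)),
    transcripts$transcript_id)
  df <- df[df$transcript_id %in% names(out), , drop = FALSE]
  for (tid in unique(df$transcript_id)) {
    g <- df[df$transcript_id == tid, ]
    keep <- g$position >= 0 & g$position < length(out[[tid]])
    out[[tid]][g$position[keep] + 1] <- g$score[keep]
  }
  out
}
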