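# Transcript/uORF data model and BED-like I/O.
#
# All coordinates are transcript-space, 0-based, half-open; a transcript is
# laid out as 5'UTR | mORF | 3'UTR with no gaps. uORF spans live in the 5'UTR
# and by default exclude the stop codon.

#' Near-cognate start codons recognised by default
#'
#' The seven codons one mismatch away from AUG that support detectable
#' initiation in yeast. AAG and AGG are deliberately absent: AAG is the
#' canonical "dead" substitution used to inactivate uORF start codons in
#' reporter mutagenesis, so both first-position purine transitions are
#' treated as non-functional.
#'
#' @export
DEFAULT_NCC_SET <- c("CTG", "GTG", "TTG", "ACG", "ATA", "ATT", "ATC")

#' Construct and validate a table of transcript models
#'
#' @param df data.frame with columns `transcript_id`, `utr5_start`,
#'   `utr5_end`, `morf_start`, `morf_end`, `utr3_start`, `utr3_end`.
#'   Transcript length is taken as `utr3_end`.
#' @return data.frame of class `transcript_models`, one row per transcript.
#' @export
transcript_models <- function(df) {
  req <- c("transcript_id", "utr5_start", "utr5_end", "morf_start",
           "morf_end", "utr3_start", "utr3_end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- df[req]
  df$length <- df$utr3_end
  bad <- validate_transcript_rows(df)
  if (length(bad)) stop("invalid transcript model(s): ",
                        paste(bad, collapse = "; "))
  if (anyDuplicated(df$transcript_id))
    stop("duplicated transcript_id in transcript models")
  df <- df[order(df$transcript_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("transcript_models", "data.frame")
  df
}

validate_transcript_rows <- function(df) {
  msgs <- character()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    id <- r$transcript_id
    if (!(r$utr5_start >= 0 && r$utr5_start <= r$utr5_end))
      msgs <- c(msgs, paste0(id, ": bad 5'UTR span"))
    if (r$utr5_end != r$morf_start)
      msgs <- c(msgs, paste0(id, ": 5'UTR end != mORF start"))
    if (r$morf_end != r$utr3_start)
      msgs <- c(msgs, paste0(id, ": mORF end != 3'UTR start"))
    if (r$morf_end < r$morf_start || r$utr3_end < r$utr3_start)
      msgs <- c(msgs, paste0(id, ": negative-length span"))
    ml <- r$morf_end - r$morf_start
    if (ml <= 0 || ml %% 3 != 0)
      msgs <- c(msgs, paste0(id, ": mORF length ", ml,
                             " is not a positive multiple of 3"))
  }
  msgs
}

#' Read transcript feature spans from a BED-like file
#'
#' Expects BED6 rows whose chrom column is the transcript id and whose name
#' column is `<transcript_id>:<kind>` with kind one of `utr5`, `morf`,
#' `utr3`. Every transcript must contribute all three rows.
#'
#' @param path path to the BED file.
#' @return `transcript_models` data.frame (empty for an empty file).
#' @export
read_transcript_features <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(transcript_models(data.frame(
      transcript_id = character(), utr5_start = integer(),
      utr5_end = integer(), morf_start = integer(), morf_end = integer(),
      utr3_start = integer(), utr3_end = integer())))
  }
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4)
      stop("parse error at line ", i, ": expected >= 4 tab-separated fields")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop("parse error at line ", i, ": non-integer coordinates")
    nm <- strsplit(f[4], ":", fixed = TRUE)[[1]]
    if (length(nm) != 2 || !nm[2] %in% c("utr5", "morf", "utr3"))
      stop("parse error at line ", i,
           ": name must be <transcript_id>:<utr5|morf|utr3>")
    rows[[i]] <- data.frame(transcript_id = nm[1], kind = nm[2],
                            start = start, end = end)
  }
  feat <- do.call(rbind, rows)
  out <- lapply(split(feat, feat$transcript_id), function(g) {
    if (!setequal(g$kind, c("utr5", "morf", "utr3")) || nrow(g) != 3)
      stop("validation error for transcript ", g$transcript_id[1],
           ": need exactly one utr5, morf and utr3 row")
    data.frame(
      transcript_id = g$transcript_id[1],
      utr5_start = g$start[g$kind == "utr5"],
      utr5_end = g$end[g$kind == "utr5"],
      morf_start = g$start[g$kind == "morf"],
      morf_end = g$end[g$kind == "morf"],
      utr3_start = g$start[g$kind == "utr3"],
      utr3_end = g$end[g$kind == "utr3"])
  })
  transcript_models(do.call(rbind, out))
}

#' Construct a uORF compilation
#'
#' @param records data.frame with columns `uorf_id`, `transcript_id`,
#'   `start`, `end`, `start_class` (`AUG` or `NCC`) and `sources`
#'   (`;`-separated tags).
#' @param provenance character vector of source dataset names.
#' @return data.frame of class `uorf_compilation`.
#' @export
uorf_compilation <- function(records, provenance = character()) {
  req <- c("uorf_id", "transcript_id", "start", "end", "start_class",
           "sources")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  records <- records[req]
  key <- paste(records$transcript_id, records$start, records$end)
  if (anyDuplicated(key))
    stop("duplicate (transcript_id, span) records within one compilation")
  records <- records[order(records$transcript_id, records$start,
                           records$end), , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "provenance") <- provenance
  class(records) <- c("uorf_compilation", "data.frame")
  records
}

#' Merge uORF compilations with exact-span deduplication
#'
#' Records sharing the same (transcript_id, span) are collapsed to a single
#' record whose `sources` field is the union of the source tags; partially
#' overlapping uORFs are distinct records and are all kept.
#'
#' @param compilations list of `uorf_compilation` objects.
#' @param transcripts optional `transcript_models`; when supplied, every
#'   record must resolve to a known transcript.
#' @return merged `uorf_compilation`, sorted by (transcript_id, start).
#' @export
merge_uorf_compilations <- function(compilations, transcripts = NULL) {
  empty <- uorf_compilation(data.frame(
    uorf_id = character(), transcript_id = character(), start = integer(),
    end = integer(), start_class = character(), sources = character()))
  if (!length(compilations)) return(empty)
  all <- do.call(rbind, lapply(compilations, as.data.frame))
  if (!nrow(all)) return(empty)
  if (!is.null(transcripts)) {
    unk <- setdiff(all$transcript_id, transcripts$transcript_id)
    if (length(unk))
      stop("uORF record(s) on unknown transcript(s): ",
           paste(unique(unk), collapse = ", "))
  }
  key <- paste(all$transcript_id, all$start, all$end)
  merged <- lapply(split(all, key), function(g) {
    src <- sort(unique(unlist(strsplit(g$sources, ";", fixed = TRUE))))
    r <- g[1, , drop = FALSE]
    r$sources <- paste(src, collapse = ";")
    r
  })
  out <- do.call(rbind, merged)
  prov <- unique(unlist(lapply(compilations, attr, "provenance")))
  uorf_compilation(out, provenance = prov)
}

#' Classify a start codon as AUG, near-cognate, or non-functional
#'
#' @param codon character vector of 3-letter codons over A/C/G/T/U.
#' @param ncc_set near-cognate codon set (DNA alphabet); defaults to
#'   [DEFAULT_NCC_SET].
#' @return character vector with values `"AUG"`, `"NCC"` or
#'   `"NONFUNCTIONAL"`.
#' @export
classify_start_codon <- function(codon, ncc_set = DEFAULT_NCC_SET) {
  codon <- chartr("Uu", "Tt", toupper(codon))
  if (any(nchar(codon) != 3) || any(grepl("[^ACGT]", codon)))
    stop("codons must be 3 letters over {A,C,G,U/T}")
  out <- rep("NONFUNCTIONAL", length(codon))
  out[codon == "ATG"] <- "AUG"
  out[codon %in% ncc_set] <- "NCC"
  out
}

#' Validate uORF records against transcript models
#'
#' Report-only check used before any downstream quantification: unknown
#' transcripts, spans outside the 5'UTR (overlap of the mORF start is allowed
#' only with `allow_morf_overlap = TRUE`), spans that are too short or not a
#' codon multiple.
#'
#' @param transcripts `transcript_models`.
#' @param uorfs `uorf_compilation`.
#' @param allow_morf_overlap allow spans to extend past the mORF start.
#' @param min_codons minimum uORF length in codons excluding the stop
#'   (default 2, the most permissive criterion among published compilations).
#' @param span_includes_stop set when imported spans carry the stop codon;
#'   the stop is then ignored for the length check.
#' @return data.frame with columns `uorf_id` and `problem`; zero rows when
#'   the annotation is consistent.
#' @export
validate_annotation <- function(transcripts, uorfs,
                                allow_morf_overlap = FALSE,
                                min_codons = 2,
                                span_includes_stop = FALSE) {
  probs <- list()
  add <- function(id, msg) probs[[length(probs) + 1]] <<-
    data.frame(uorf_id = id, problem = msg)
  tx <- as.data.frame(transcripts)
  rownames(tx) <- tx$transcript_id
  for (i in seq_len(nrow(uorfs))) {
    u <- uorfs[i, ]
    if (!u$transcript_id %in% tx$transcript_id) {
      add(u$uorf_id, paste0("unknown transcript ", u$transcript_id))
      next
    }
    t <- tx[u$transcript_id, ]
    len <- u$end - u$start
    eff_len <- if (span_includes_stop) len - 3 else len
    if (u$start < 0 || u$end > t$length)
      add(u$uorf_id, "span outside transcript")
    if (u$start >= t$utr5_end)
      add(u$uorf_id, "start not within 5'UTR")
    if (!allow_morf_overlap && u$end > t$morf_start)
      add(u$uorf_id, "span extends past mORF start")
    if (eff_len < 3 * min_codons || eff_len %% 3 != 0)
      add(u$uorf_id, paste0("length ", len, " nt invalid (need multiple of",
                            " 3 and >= ", min_codons, " codons)"))
    if (!u$start_class %in% c("AUG", "NCC"))
      add(u$uorf_id, paste0("bad start_class ", u$start_class))
  }
  if (!length(probs))
    return(data.frame(uorf_id = character(), problem = character()))
  out <- do.call(rbind, probs)
  rownames(out) <- NULL
  out
}

#' Write a uORF compilation as BED6
#'
#' chrom = transcript id, name = uORF id, score = 0, strand = "+".
#' @param uorfs `uorf_compilation`.
#' @param path output path.
#' @export
write_uorf_bed <- function(uorfs, path) {
  df <- data.frame(uorfs$transcript_id, uorfs$start, uorfs$end,
                   uorfs$uorf_id, 0L, "+")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a uORF BED6 file into a compilation
#'
#' @param path BED6 path (chrom = transcript id, name = uORF id).
#' @param source tag recorded in the `sources` field of every record.
#' @param start_class either a single class for all records or a vector.
#' @export
read_uorf_bed <- function(path, source = basename(path),
                          start_class = "NCC") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df))
    return(uorf_compilation(data.frame(
      uorf_id = character(), transcript_id = character(), start = integer(),
      end = integer(), start_class = character(), sources = character()),
      provenance = source))
  uorf_compilation(data.frame(
    uorf_id = df[[4]], transcript_id = df[[1]], start = df[[2]],
    end = df[[3]], start_class = start_class, sources = source),
    provenance = source)
}
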