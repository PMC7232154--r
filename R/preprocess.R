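# Adapter/quality trimming and length filtering.

#' Trim a 3' adapter from one read
#'
#' Finds the leftmost suffix of the read that aligns to a prefix of the
#' adapter with mismatch fraction at most `max_error_rate` and overlap at
#' least `min_overlap`, and removes it (together with everything 3' of the
#' match start). When the read runs past the full adapter, only the adapter
#' portion is compared and the whole tail is removed. Qualities, when given,
#' are truncated in lockstep. No match leaves the read unchanged.
#'
#' @param sequence Read sequence (character scalar).
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum adapter/read overlap to accept a match.
#' @param max_error_rate Maximum mismatch fraction within the overlap.
#' @param qualities Optional integer Phred vector, same length as `sequence`.
#' @return List with `sequence` and `qualities` after trimming.
#' @export
trim_adapter <- function(sequence, adapter, min_overlap = 3L,
                         max_error_rate = 0.1, qualities = NULL) {
  stopifnot(nzchar(adapter), min_overlap >= 1L)
  cut <- adapter_match_start(sequence, adapter, min_overlap, max_error_rate)
  if (cut <= nchar(sequence)) {
    sequence <- substr(sequence, 1L, cut - 1L)
    if (!is.null(qualities)) qualities <- qualities[seq_len(cut - 1L)]
  }
  list(sequence = sequence, qualities = qualities)
}

# 1-based position of the first removed base, or nchar(sequence)+1 if none.
adapter_match_start <- function(sequence, adapter, min_overlap, max_error_rate) {
  L <- nchar(sequence)
  A <- nchar(adapter)
  if (L == 0L) return(1L)
  sr <- charToRaw(sequence)
  ar <- charToRaw(adapter)
  for (i in seq_len(L)) {
    ov <- min(L - i + 1L, A)
    if (ov < min_overlap) break
    mm <- sum(sr[i:(i + ov - 1L)] != ar[seq_len(ov)])
    if (mm <= max_error_rate * ov) return(i)
  }
  L + 1L
}

#' Quality-trim the 3' end of a read
#'
#' BWA-style running-sum rule: among all candidate cut points, remove the
#' suffix maximizing the sum of `(threshold - q)` over removed bases; when no
#' suffix has a positive sum (e.g. an all-high-quality read) the read is
#' unchanged. Ties favor the longer trim.
#'
#' @param sequence Read sequence.
#' @param qualities Integer Phred scores, same length as `sequence`.
#' @param threshold Phred threshold (default 20).
#' @return List with `sequence` and `qualities` after trimming.
#' @export
quality_trim <- function(sequence, qualities, threshold = 20L) {
  stopifnot(length(qualities) == nchar(sequence), threshold >= 0)
  keep <- quality_trim_keep(qualities, threshold)
  list(sequence = substr(sequence, 1L, keep),
       qualities = qualities[seq_len(keep)])
}

# number of bases kept from the 5' end
quality_trim_keep <- function(qualities, threshold) {
  L <- length(qualities)
  if (L == 0L) return(0L)
  s <- rev(cumsum(rev(threshold - qualities)))  # s[k] = sum over suffix k..L
  k <- which.max(s)                             # first (longest) maximizing cut
  if (s[k] > 0) k - 1L else L
}

#' Apply the length window to a trimmed read
#'
#' @param sequence Trimmed read sequence.
#' @param original_length Length of the raw read before trimming.
#' @param min_len,max_len Inclusive length bounds (defaults 19 and 33 nt,
#'   the gel excision window of small RNA library preps).
#' @param quality_trimmed Logical; whether quality trimming removed bases
#'   (used to attribute too-short reads to `low_quality`).
#' @return List (`trimmed_read`): `sequence`, `original_length`, `kept`,
#'   `discard_reason` in `none`/`too_short`/`too_long`/`low_quality`.
#' @export
length_filter <- function(sequence, original_length = nchar(sequence),
                          min_len = 19L, max_len = 33L,
                          quality_trimmed = FALSE) {
  L <- nchar(sequence)
  reason <- "none"
  kept <- TRUE
  if (L < min_len) {
    kept <- FALSE
    reason <- if (quality_trimmed) "low_quality" else "too_short"
  } else if (L > max_len) {
    kept <- FALSE
    reason <- "too_long"
  }
  list(sequence = sequence, original_length = original_length,
       kept = kept, discard_reason = reason)
}

#' Trim one read through the full pipeline
#'
#' Order of operations: adapter trim, then quality trim, then length filter
#' (adapters carry synthetic qualities, so they are removed first).
#'
#' @inheritParams trim_adapter
#' @inheritParams quality_trim
#' @inheritParams length_filter
#' @return As [length_filter()], plus `qualities`.
#' @export
trim_read <- function(sequence, qualities, adapter = "AGATCGGAAGAGC",
                      min_overlap = 3L, max_error_rate = 0.1,
                      quality_cutoff = 20L, min_len = 19L, max_len = 33L) {
  orig <- nchar(sequence)
  a <- if (nzchar(adapter)) {
    trim_adapter(sequence, adapter, min_overlap, max_error_rate, qualities)
  } else list(sequence = sequence, qualities = qualities)
  q <- quality_trim(a$sequence, a$qualities, quality_cutoff)
  out <- length_filter(q$sequence, original_length = orig,
                       min_len = min_len, max_len = max_len,
                       quality_trimmed = nchar(q$sequence) < nchar(a$sequence))
  out$qualities <- q$qualities
  out
}

#' Trim a FASTQ file
#'
#' Applies [trim_read()] to every record, writes kept reads to `output`
#' (Phred+33 FASTQ) and returns a QC report.
#'
#' @param input Input FASTQ path (plain or gzip).
#' @param output Output FASTQ path for kept reads, or `NULL` to skip writing.
#' @inheritParams trim_read
#' @return Object of class `qc_report`: `reads_in`, `reads_kept`, `discards`
#'   (named counts per reason), `length_histogram` (post-trim lengths of kept
#'   reads, 19-33), plus `ids`, `sequences` and `lengths` of the kept reads.
#' @export
trim_fastq <- function(input, output = NULL, adapter = "AGATCGGAAGAGC",
                       min_overlap = 3L, max_error_rate = 0.1,
                       quality_cutoff = 20L, min_len = 19L, max_len = 33L) {
  fq <- read_fastq(input)
  n <- length(fq$sequence)
  kept <- logical(n)
  reasons <- character(n)
  seqs <- character(n)
  quals <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- trim_read(fq$sequence[i], fq$quality[[i]], adapter = adapter,
                    min_overlap = min_overlap, max_error_rate = max_error_rate,
                    quality_cutoff = quality_cutoff,
                    min_len = min_len, max_len = max_len)
    kept[i] <- tr$kept
    reasons[i] <- tr$discard_reason
    seqs[i] <- tr$sequence
    quals[[i]] <- tr$qualities
  }
  if (!is.null(output)) {
    ks <- seqs[kept]
    if (length(ks)) {
      dna <- Biostrings::DNAStringSet(ks)
      names(dna) <- fq$id[kept]
      qstr <- vapply(quals[kept], function(q) rawToChar(as.raw(q + 33L)),
                     character(1))
      Biostrings::writeXStringSet(dna, output, format = "fastq",
                                  qualities = Biostrings::BStringSet(qstr))
    } else {
      writeLines(character(0), output)
    }
  }
  discards <- table(factor(reasons[!kept],
                           levels = c("too_short", "too_long", "low_quality")))
  hist <- table(factor(nchar(seqs[kept]), levels = min_len:max_len))
  structure(list(reads_in = n,
                 reads_kept = sum(kept),
                 discards = stats::setNames(as.integer(discards), names(discards)),
                 length_histogram = stats::setNames(as.integer(hist), names(hist)),
                 ids = fq$id[kept],
                 sequences = seqs[kept],
                 lengths = nchar(seqs[kept])),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Small RNA trimming QC\n")
  cat(sprintf("  reads in:   %d\n", x$reads_in))
  cat(sprintf("  reads kept: %d\n", x$reads_kept))
  for (r in names(x$discards)) {
    cat(sprintf("  discarded (%s): %d\n", r, x$discards[[r]]))
  }
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report`.
#' @param path Output TSV path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("reads_in", "reads_kept",
               paste0("discarded_", names(report$discards)),
               paste0("kept_length_", names(report$length_histogram))),
    value = c(report$reads_in, report$reads_kept,
              report$discards, report$length_histogram))
  write_tsv(df, path)
}
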