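# One-mismatch short read alignment via pigeonhole seeding.
#
# A read with at most one mismatch against the reference has at least one of
# its two terminal 9-mers (which never overlap for reads >= 18 nt) matching
# the reference exactly, so exact lookup of both end seeds enumerates every
# candidate placement; candidates are then verified by full Hamming
# comparison. Internal coordinates are 0-based half-open; SAM output is
# 1-based.

#' Build an exact-match seed index over a reference
#'
#' Hashes every `seed_len`-mer of the reference (seeds containing N are not
#' indexed: N always counts as a mismatch, so an N-containing window can
#' never be the exact half of a <=1-mismatch placement).
#'
#' @param sequence Reference sequence (character scalar over ACGTN).
#' @param name Reference name carried into alignment records.
#' @param seed_len Seed length; the default 9 is half the minimum read
#'   length of the 19-33 nt window.
#' @return Object of class `reference_index`.
#' @export
build_index <- function(sequence, name = "ref", seed_len = 9L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  G <- nchar(sequence)
  if (G == 0L) stop("empty reference sequence")
  if (G < seed_len) stop("reference shorter than the seed length")
  starts0 <- 0:(G - seed_len)
  seeds <- substring(sequence, starts0 + 1L, starts0 + seed_len)
  ok <- !grepl("N", seeds, fixed = TRUE)
  tab <- split(starts0[ok], seeds[ok])
  env <- list2env(tab, hash = TRUE)
  structure(list(name = name, sequence = sequence, length = G,
                 seed_len = as.integer(seed_len), table = env,
                 raw = charToRaw(sequence)),
            class = "reference_index")
}

#' Look up the exact positions of a seed in the index
#'
#' @param index A [build_index()] result.
#' @param seed Seed string of length `index$seed_len`.
#' @return Sorted integer vector of 0-based reference positions.
#' @export
index_lookup <- function(index, seed) {
  stopifnot(nchar(seed) == index$seed_len)
  hits <- index$table[[seed]]
  if (is.null(hits)) integer(0) else sort(hits)
}

# Candidate enumeration shared by every alignment path. `fwd` is the read as
# sequenced, `rev` its reverse complement; returns parallel vectors.
enumerate_candidates <- function(fwd, rev, index, max_mismatches = 1L) {
  k <- index$seed_len
  G <- index$length
  refraw <- index$raw
  tab <- index$table
  strands <- character(0)
  starts <- integer(0)
  mms <- integer(0)
  L <- nchar(fwd)
  if (L >= 2L * k && L <= G) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      sr <- charToRaw(s)
      cand <- c(tab[[substr(s, 1L, k)]],
                tab[[substr(s, L - k + 1L, L)]] - (L - k))
      if (!is.null(cand)) {
        cand <- unique(cand[cand >= 0L & cand + L <= G])
        for (c0 in cand) {
          mm <- count_mismatches_raw(refraw[(c0 + 1L):(c0 + L)], sr)
          if (mm <= max_mismatches) {
            strands <- c(strands, strand)
            starts <- c(starts, as.integer(c0))
            mms <- c(mms, mm)
          }
        }
      }
    }
  }
  list(strand = strands, start = starts, mismatches = mms)
}

#' Enumerate all placements of a read with at most `max_mismatches`
#'
#' Both strands are searched (the read is reverse-complemented for the `-`
#' strand); N in read or reference counts as a mismatch.
#'
#' @param sequence Read sequence (as sequenced).
#' @param index A `reference_index`.
#' @param max_mismatches 0 or 1 (the pigeonhole guarantee holds for <=1).
#' @return `data.frame` with columns `strand`, `start` (0-based), `mismatches`.
#' @export
align_candidates <- function(sequence, index, max_mismatches = 1L) {
  stopifnot(max_mismatches %in% c(0L, 1L))
  cand <- enumerate_candidates(sequence, revcomp(sequence), index,
                               max_mismatches)
  data.frame(strand = cand$strand, start = cand$start,
             mismatches = cand$mismatches)
}

#' Align one read to one reference
#'
#' Reports a single placement: candidates are stratified by mismatch count
#' (0 beats 1) and ties within the best stratum are broken uniformly at
#' random using the current RNG state ([align_library()] seeds it).
#'
#' @inheritParams align_candidates
#' @param read_id Identifier carried into the record.
#' @return One-row `data.frame` (an alignment record: `read_id`, `reference`,
#'   `strand`, `start`, `read_length`, `mismatches`, `sequence` in
#'   reference-forward orientation), or `NULL` when unmapped.
#' @export
align_read <- function(sequence, index, read_id = "read",
                       max_mismatches = 1L) {
  rev <- revcomp(sequence)
  cand <- enumerate_candidates(sequence, rev, index, max_mismatches)
  if (length(cand$start) == 0L) return(NULL)
  best <- which(cand$mismatches == min(cand$mismatches))
  pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
  data.frame(read_id = read_id, reference = index$name,
             strand = cand$strand[pick], start = cand$start[pick],
             read_length = nchar(sequence),
             mismatches = cand$mismatches[pick],
             sequence = if (cand$strand[pick] == "+") sequence else rev)
}

#' Align a trimmed library against each viral reference
#'
#' Every read is aligned to every reference independently (a read may count
#' on more than one virus, mirroring per-genome mapping); each kept read
#' contributes at most one placement per reference, chosen from the best
#' mismatch stratum with a seeded random tie-break.
#'
#' @param ids Character vector of read identifiers.
#' @param sequences Character vector of read sequences (same length).
#' @param indexes Named list of `reference_index` objects, one per virus.
#' @param library_total Total kept reads of the library (RPM denominator);
#'   must be positive.
#' @param seed Integer seed for tie-breaking.
#' @param max_mismatches 0 or 1.
#' @return Object of class `library_alignment`: `records` (named list of
#'   per-reference alignment data.frames), `unmapped` (named counts),
#'   `library_total`.
#' @export
align_library <- function(ids, sequences, indexes, library_total,
                          seed = 1L, max_mismatches = 1L) {
  stopifnot(length(ids) == length(sequences))
  if (library_total <= 0L) stop("library_total must be positive (RPM undefined)")
  if (is.null(names(indexes))) {
    names(indexes) <- vapply(indexes, `[[`, character(1), "name")
  }
  n <- length(sequences)
  revs <- if (n) revcomp(sequences) else character(0)
  withr::with_seed(seed, {
    records <- lapply(indexes, function(idx) {
      strand <- character(n)
      start <- integer(n)
      mm <- integer(n)
      hit <- logical(n)
      for (i in seq_len(n)) {
        cand <- enumerate_candidates(sequences[i], revs[i], idx, max_mismatches)
        if (length(cand$start) == 0L) next
        best <- which(cand$mismatches == min(cand$mismatches))
        pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
        strand[i] <- cand$strand[pick]
        start[i] <- cand$start[pick]
        mm[i] <- cand$mismatches[pick]
        hit[i] <- TRUE
      }
      data.frame(read_id = ids[hit], reference = rep(idx$name, sum(hit)),
                 strand = strand[hit], start = start[hit],
                 read_length = nchar(sequences[hit]), mismatches = mm[hit],
                 sequence = ifelse(strand[hit] == "+",
                                   sequences[hit], revs[hit]))
    })
    unmapped <- vapply(records, function(r) n - nrow(r), integer(1))
    structure(list(records = records, unmapped = unmapped,
                   library_total = library_total),
              class = "library_alignment")
  })
}

#' Write alignments as SAM
#'
#' Emits `@HD`/`@SQ` headers and one line per record: `POS` is 1-based,
#' `FLAG` 16 marks `-` strand placements, `SEQ` is in reference-forward
#' orientation (reverse complement of the sequenced read for `-` strand),
#' and the `NM` tag carries the mismatch count.
#'
#' @param alignment A `library_alignment`.
#' @param indexes The named list of `reference_index` objects used to
#'   produce it (for `@SQ` lengths).
#' @param path Output SAM path.
#' @export
write_sam <- function(alignment, indexes, path) {
  stopifnot(inherits(alignment, "library_alignment"))
  if (is.null(names(indexes))) {
    names(indexes) <- vapply(indexes, `[[`, character(1), "name")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(alignment$records)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, indexes[[nm]]$length), con)
  }
  for (nm in names(alignment$records)) {
    r <- alignment$records[[nm]]
    if (nrow(r) == 0L) next
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                     r$read_id, ifelse(r$strand == "-", 16L, 0L), nm,
                     r$start + 1L, r$read_length, r$sequence, r$mismatches)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Parse a SAM file back into alignment records
#'
#' Counterpart of [write_sam()] for round-trip checks and downstream reuse;
#' only single-segment, ungapped records as written by this package are
#' supported.
#'
#' @param path SAM path.
#' @return `data.frame` of alignment records (as in [align_read()]).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) {
    return(data.frame(read_id = character(0), reference = character(0),
                      strand = character(0), start = integer(0),
                      read_length = integer(0), mismatches = integer(0),
                      sequence = character(0)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[12:length(x)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  seqs <- vapply(f, `[[`, character(1), 10)
  data.frame(
    read_id = vapply(f, `[[`, character(1), 1),
    reference = vapply(f, `[[`, character(1), 3),
    strand = ifelse(bitwAnd(as.integer(vapply(f, `[[`, character(1), 2)), 16L) > 0L,
                    "-", "+"),
    start = as.integer(vapply(f, `[[`, character(1), 4)) - 1L,
    read_length = nchar(seqs),
    mismatches = nm,
    sequence = seqs)
}
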