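# Independent oracles and fixture builders shared across test files. The
# oracles deliberately use different machinery (character vectors, exhaustive
# scans, outer products) from the implementation paths they check.

# Exhaustive <=max_mm placement scan: every start x both strands, mismatches
# counted per position with N always mismatching. Vectorized over starts.
oracle_candidates <- function(sequence, reference, max_mm = 1L) {
  G <- nchar(reference)
  refc <- strsplit(reference, "", fixed = TRUE)[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    L <- nchar(s)
    if (L > G) next
    sc <- strsplit(s, "", fixed = TRUE)[[1]]
    starts <- 0:(G - L)
    mm <- integer(length(starts))
    for (j in seq_len(L)) {
      rj <- refc[starts + j]
      mm <- mm + (rj != sc[j] | rj == "N" | sc[j] == "N")
    }
    keep <- mm <= max_mm
    if (any(keep)) {
      out[[strand]] <- data.frame(strand = strand, start = starts[keep],
                                  mismatches = mm[keep])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(strand = character(0), start = integer(0),
                      mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# canonical ordering so candidate sets can be compared exactly
sort_candidates <- function(df) {
  df <- df[order(df$strand, df$start, df$mismatches), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Leftmost adapter-match scan written against character vectors.
oracle_adapter_start <- function(sequence, adapter, min_overlap, max_error_rate) {
  L <- nchar(sequence)
  sc <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ac <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (i in seq_len(L)) {
    ov <- min(L - i + 1L, length(ac))
    if (ov < min_overlap) break
    mism <- sum(sc[i:(i + ov - 1L)] != ac[seq_len(ov)])
    if (mism / ov <= max_error_rate) return(i)
  }
  L + 1L
}

# Exhaustive quality-trim oracle: evaluate every cut point, keep the suffix
# with the largest positive sum of (threshold - q); ties -> longest trim.
oracle_quality_keep <- function(qual, threshold) {
  L <- length(qual)
  if (L == 0L) return(0L)
  keeps <- 0:(L - 1L)
  sums <- vapply(keeps, function(k) sum(threshold - qual[(k + 1L):L]),
                 numeric(1))
  m <- max(sums)
  if (m > 0) keeps[which(sums == m)[1L]] else L   # tie -> longest trim
}

# Quadratic all-pairs ping-pong oracle (raw pair counting).
oracle_pingpong_raw <- function(alignments, length_class = 26:30) {
  sel <- alignments[alignments$read_length %in% length_class, , drop = FALSE]
  plus5 <- sel$start[sel$strand == "+"]
  minus5 <- sel$start[sel$strand == "-"] +
    sel$read_length[sel$strand == "-"] - 1L
  counts <- numeric(20)
  if (length(plus5) && length(minus5)) {
    ov <- outer(minus5, plus5, function(q, p) q - p + 1L)
    ov <- ov[ov >= 1L & ov <= 20L]
    if (length(ov)) counts <- tabulate(ov, 20L)
  }
  counts
}

# Two-sided exact binomial p-value by direct summation of the pmf.
oracle_binom_two_sided <- function(count, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[count + 1L] * (1 + 1e-7)])
}

# Alignment records constructed directly from simulated reads (ground truth
# placement, zero mismatches) -- used where profile/signature behavior is
# under test rather than the aligner.
records_from_sim <- function(reads, reference = "virus") {
  if (nrow(reads) == 0L) {
    return(data.frame(read_id = character(0), reference = character(0),
                      strand = character(0), start = integer(0),
                      read_length = integer(0), mismatches = integer(0),
                      sequence = character(0)))
  }
  fwd <- ifelse(reads$strand == "+", reads$sequence, revcomp(reads$sequence))
  data.frame(read_id = sprintf("r%06d", seq_len(nrow(reads))),
             reference = reference, strand = reads$strand,
             start = reads$start, read_length = reads$length,
             mismatches = 0L, sequence = fwd)
}

# uniform random genome of a given length
random_genome <- function(len, seed) {
  generate_genome(genome_spec("rnd", len), seed)
}

# substitute exactly one base at 1-based position pos
substitute_base <- function(sequence, pos) {
  b <- substr(sequence, pos, pos)
  repl <- setdiff(c("A", "C", "G", "T"), b)[sample.int(3L, 1L)]
  paste0(substr(sequence, 1L, pos - 1L), repl,
         substr(sequence, pos + 1L, nchar(sequence)))
}
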