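# piRNA signature analytics: positional nucleotide frequency matrices,
# 1U/10A binomial bias tests, and ping-pong 5'-overlap histograms.

#' Positional nucleotide frequency matrix of a read class
#'
#' Reads are anchored at their 5' ends; position 1 is the biological 5'
#' nucleotide. For `-` strand placements the read-space sequence (reverse
#' complement of the stored reference-forward sequence) is used. T is
#' reported as U. Coverage at a position is the number of reads long enough
#' to reach it, so it is non-increasing along positions.
#'
#' @param alignments Alignment record `data.frame` (one reference).
#' @param strand `"+"` or `"-"`: which placements to use.
#' @param length_class Read lengths included (default 26:30, the vpiRNA
#'   candidate window).
#' @param max_position Number of positions reported (default
#'   `max(length_class)`).
#' @return Object of class `frequency_matrix`: `freq` and `counts`
#'   (position x A/C/G/U matrices), `coverage` (per position), `strand`,
#'   `n_reads`. Frequencies are `NA` where coverage is zero.
#' @export
nucleotide_frequency_matrix <- function(alignments, strand,
                                        length_class = 26:30,
                                        max_position = max(length_class)) {
  stopifnot(strand %in% c("+", "-"))
  sel <- alignments[alignments$strand == strand &
                      alignments$read_length %in% length_class, , drop = FALSE]
  L <- as.integer(max_position)
  counts <- matrix(0L, nrow = L, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "U")))
  coverage <- integer(L)
  if (nrow(sel)) {
    reads <- if (strand == "+") sel$sequence else revcomp(sel$sequence)
    for (p in seq_len(L)) {
      b <- substr(reads, p, p)
      b <- b[b != ""]
      coverage[p] <- length(b)
      if (length(b)) {
        tb <- table(factor(b, levels = c("A", "C", "G", "T")))
        counts[p, ] <- as.integer(tb)
      }
    }
  }
  freq <- counts / ifelse(coverage > 0, coverage, NA_integer_)
  structure(list(freq = freq, counts = counts, coverage = coverage,
                 strand = strand, n_reads = nrow(sel),
                 length_class = length_class),
            class = "frequency_matrix")
}

#' Base composition of one strand of a genome, in read space
#'
#' The expected background for positional nucleotide frequencies of reads
#' from that strand: for `+` the genome's own composition, for `-` the
#' composition of its complement. T is reported as U.
#'
#' @param genome Reference sequence (character scalar).
#' @param strand `"+"` or `"-"`.
#' @return Named numeric over `A`, `C`, `G`, `U`, summing to 1.
#' @export
strand_base_composition <- function(genome, strand = c("+", "-")) {
  strand <- match.arg(strand)
  p <- base_frequencies(genome)                 # A C G T of the deposited seq
  out <- if (strand == "+") p else p[c("T", "G", "C", "A")]
  names(out) <- c("A", "C", "G", "U")
  out
}

#' Exact binomial test for a positional nucleotide bias
#'
#' Two-sided exact binomial test of the observed count of `nucleotide` at
#' `position` against a background frequency (by default the strand's
#' genomic base composition, since viral genomes are compositionally skewed
#' and 0.25 would misstate the null). A position is flagged biased when the
#' test rejects at `alpha` *and* the observed frequency exceeds background.
#'
#' @param matrix A [nucleotide_frequency_matrix()].
#' @param position Read position tested (1 for 1U, 10 for 10A).
#' @param nucleotide `"U"` or `"A"` (any of A/C/G/U accepted).
#' @param background Null frequency of the nucleotide.
#' @param alpha Significance level (default 0.01).
#' @return List of class `bias_result`: `position`, `nucleotide`,
#'   `observed_frequency`, `coverage`, `background`, `p_value`, `biased`.
#' @export
bias_test <- function(matrix, position, nucleotide, background, alpha = 0.01) {
  stopifnot(inherits(matrix, "frequency_matrix"),
            nucleotide %in% c("A", "C", "G", "U"),
            background > 0, background < 1)
  cov <- unname(matrix$coverage[position])
  if (is.na(cov) || cov == 0L) stop("no coverage at the tested position")
  count <- unname(matrix$counts[position, nucleotide])
  freq <- count / cov
  p <- stats::binom.test(count, cov, p = background,
                         alternative = "two.sided")$p.value
  structure(list(position = position, nucleotide = nucleotide,
                 observed_frequency = freq, coverage = cov,
                 background = background, p_value = p,
                 biased = (p < alpha) && (freq > background)),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("%d%s bias: freq %.3f vs background %.3f (coverage %d), p = %.3g -> %s\n",
              x$position, x$nucleotide, x$observed_frequency, x$background,
              x$coverage, x$p_value, if (x$biased) "BIASED" else "not biased"))
  invisible(x)
}

#' Ping-pong 5'-overlap histogram
#'
#' For every pair of opposite-strand placements, the 5'-to-5' overlap in
#' reference space is `q - p + 1` nt, where `p` is the 5' end of the `+`
#' read (leftmost position) and `q` the 5' end of the `-` read (rightmost
#' position). Overlaps of 1-20 nt are binned; ping-pong amplification puts
#' the mass at 10.
#'
#' Pair weighting: in `"weighted"` mode (default) each distinct
#' `(p, q)` 5'-position pair contributes `min(multiplicity)` of the two
#' ends, damping amplification artifacts from many identical reads; `"raw"`
#' counts all read pairs (`n_p * n_q`), matching the quadratic all-pairs
#' enumeration exactly.
#'
#' `z10` standardizes bin 10 against bins 1-9 and 11-20 (their empirical
#' mean and SD; no parametric null) and is `NA` unless at least two of
#' those bins are nonzero.
#'
#' @param alignments Alignment record `data.frame` (one reference).
#' @param length_class Read lengths included (default 26:30).
#' @param mode `"weighted"` or `"raw"`.
#' @return Object of class `overlap_histogram`: `overlap` (1:20), `count`,
#'   `z10`, `mode`, `argmax` (overlap with the largest count; `NA` when all
#'   bins are empty).
#' @export
pingpong_overlap <- function(alignments, length_class = 26:30,
                             mode = c("weighted", "raw")) {
  mode <- match.arg(mode)
  sel <- alignments[alignments$read_length %in% length_class, , drop = FALSE]
  plus5 <- sel$start[sel$strand == "+"]
  minus5 <- sel$start[sel$strand == "-"] +
    sel$read_length[sel$strand == "-"] - 1L
  counts <- numeric(20)
  if (length(plus5) && length(minus5)) {
    maxpos <- max(plus5, minus5) + 21L
    np <- tabulate(plus5 + 1L, maxpos)
    nq <- tabulate(minus5 + 1L, maxpos)
    for (o in 1:20) {
      # pairs with q = p + o - 1
      p_idx <- seq_len(maxpos - o + 1L)
      q_idx <- p_idx + o - 1L
      w <- if (mode == "weighted") pmin(np[p_idx], nq[q_idx])
           else np[p_idx] * nq[q_idx]
      counts[o] <- sum(w)
    }
  }
  others <- counts[-10]
  z10 <- if (sum(others > 0) >= 2) {
    (counts[10] - mean(others)) / stats::sd(others)
  } else NA_real_
  structure(list(overlap = 1:20, count = counts, z10 = z10, mode = mode,
                 argmax = if (any(counts > 0)) which.max(counts) else NA_integer_),
            class = "overlap_histogram")
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat(sprintf("Ping-pong 5'-overlap histogram (%s pairs)\n", x$mode))
  cat(sprintf("  argmax bin: %s, z10 = %s\n",
              ifelse(is.na(x$argmax), "NA", x$argmax),
              ifelse(is.na(x$z10), "NA", sprintf("%.2f", x$z10))))
  invisible(x)
}

#' Write a frequency matrix as TSV
#'
#' Columns: position, A, C, G, U, coverage.
#'
#' @param matrix A [nucleotide_frequency_matrix()].
#' @param path Output TSV path.
#' @export
write_frequency_tsv <- function(matrix, path) {
  df <- data.frame(position = seq_along(matrix$coverage),
                   A = matrix$freq[, "A"], C = matrix$freq[, "C"],
                   G = matrix$freq[, "G"], U = matrix$freq[, "U"],
                   coverage = matrix$coverage)
  write_tsv(df, path)
}

#' Heat-map style plot of a frequency matrix
#'
#' @param x A [nucleotide_frequency_matrix()].
#' @param main Plot title.
#' @param ... Ignored.
#' @export
plot.frequency_matrix <- function(x, main = "positional nucleotide frequency", ...) {
  m <- x$freq
  m[is.na(m)] <- 0
  graphics::image(z = m, x = seq_len(nrow(m)), y = 1:4,
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "read position (nt from 5' end)", ylab = "",
                  yaxt = "n", main = main)
  graphics::axis(2, at = 1:4, labels = colnames(m), las = 1)
  invisible(x)
}
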