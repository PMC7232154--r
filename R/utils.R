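# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

BASES <- c("A", "C", "G", "T")
RAW_N <- charToRaw("N")

#' Reverse complement of DNA character strings
#'
#' Vectorized reverse complement over `A/C/G/T/N` character strings.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Complement (no reversal) of a character vector of single bases.
complement_bases <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

# Hamming mismatches between two raw vectors of equal length; any N on either
# side counts as a mismatch (even N vs N).
count_mismatches_raw <- function(a, b) {
  sum(a != b | a == RAW_N | b == RAW_N)
}

# Frequencies of A, C, G, T in a sequence string (named, sums to 1).
base_frequencies <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = BASES))
  n <- sum(tab)
  if (n == 0L) stop("sequence contains no A/C/G/T bases")
  as.numeric(tab) / n -> p
  names(p) <- BASES
  p
}

# Write a data.frame as a TSV with header, no quoting, no row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
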