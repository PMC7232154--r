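#' Describe a viral reference genome for simulation
#'
#' A `genome_spec` captures what the simulator needs to emit a reference:
#' its length, polarity label (the orientation of the deposited sequence),
#' gene/UTR intervals for annotation and hotspot placement, and a base
#' composition from which the sequence is drawn.
#'
#' @param name Unique identifier for the genome (e.g. `"MERV"`).
#' @param length Genome length in nucleotides (positive integer).
#' @param sense Polarity of the deposited sequence, `"positive"` or
#'   `"negative"`. This is an annotation only: alignment strand is always
#'   defined relative to the deposited sequence.
#' @param genes Optional `data.frame` with columns `label`, `start`, `end`
#'   (0-based, half-open intervals on the reference).
#' @param base_composition Named numeric probabilities over `A`, `C`, `G`,
#'   `T`; must sum to 1.
#' @return An object of class `genome_spec`.
#' @examples
#' gs <- genome_spec("MERV", 11000, sense = "negative")
#' @export
genome_spec <- function(name, length,
                        sense = c("positive", "negative"),
                        genes = NULL,
                        base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sense <- match.arg(sense)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) stop("genome length must be a positive integer")
  if (!all(sort(names(base_composition)) == BASES) ||
      abs(sum(base_composition) - 1) > 1e-9 || any(base_composition < 0)) {
    stop("base_composition must be named probabilities over A,C,G,T summing to 1")
  }
  if (!is.null(genes)) {
    stopifnot(is.data.frame(genes),
              all(c("label", "start", "end") %in% names(genes)))
    if (any(genes$start < 0L) || any(genes$end > length) ||
        any(genes$start >= genes$end)) {
      stop("gene intervals must satisfy 0 <= start < end <= length")
    }
  }
  structure(list(name = name, length = length, sense = sense,
                 genes = genes,
                 base_composition = base_composition[BASES]),
            class = "genome_spec")
}

#' Generate a reference sequence from a genome specification
#'
#' Draws an i.i.d. sequence over `A/C/G/T` from the spec's base composition.
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @return A single character string of length `spec$length`.
#' @export
generate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(seed, {
    paste0(sample(BASES, spec$length, replace = TRUE,
                  prob = spec$base_composition),
           collapse = "")
  })
}

#' Write reference genomes to FASTA
#'
#' @param sequences Named character vector of genome sequences.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(sequences, path) {
  dna <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read reference genomes from FASTA
#'
#' @param path FASTA path (one record per virus).
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- as.character(dna)
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}

#' Write gene annotations as BED (0-based, half-open)
#'
#' @param spec A [genome_spec()] with a non-`NULL` `genes` table.
#' @param path Output BED path.
#' @export
write_gene_bed <- function(spec, path) {
  stopifnot(inherits(spec, "genome_spec"))
  g <- spec$genes
  if (is.null(g) || nrow(g) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = spec$name, start = g$start, end = g$end,
                    name = g$label)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED annotation file
#'
#' @param path BED path (first four columns used).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
read_gene_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), label = character(0)))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             label = if (ncol(bed) >= 4) bed[[4]] else NA_character_)
}
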