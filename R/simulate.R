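# Small RNA library simulator.
#
# Reads are always exact genomic windows (or reverse complements of windows):
# the 1U bias of primary piRNAs and the 10A of ping-pong partners are realized
# by *conditional sampling* of 5'-end positions (a primary read starts on a
# genomic T with probability p_1U; a partner whose 5' end overlaps a 1U
# primary by exactly 10 nt then carries a 10A by complementarity). With
# sequencing_error_rate = 0 every emitted insert is therefore an exact
# substring, or reverse complement of a substring, of its source genome.

#' Parameters of one simulated read class
#'
#' @param class_label One of `"vsiRNA"`, `"vpiRNA_primary"`,
#'   `"vpiRNA_secondary"`, `"degradation"`, `"background"`.
#' @param count Number of reads to emit (non-negative integer).
#' @param length_dist Named numeric of probabilities over lengths 19-33 nt.
#'   Defaults per class: vsiRNA is a point mass at 21 nt; both vpiRNA classes
#'   and degradation are uniform over 26-30 nt; background is a miRNA/piRNA
#'   style mixture over 21-22 nt and 27-30 nt.
#' @param strand_fraction_positive Fraction of reads drawn from the positive
#'   (deposited reference) strand.
#' @param positional_weights Optional per-position sampling weights for read
#'   5' ends over the genome (length = genome length); uniform if `NULL`.
#'   Hotspots are expressed here, e.g. 10x weight over a UTR interval.
#' @param p_1U Probability that the 5' nucleotide is U (genomic T); used by
#'   `vpiRNA_primary` only.
#' @param pingpong_fraction Fraction of `vpiRNA_secondary` reads generated as
#'   exact 10-nt 5'-overlap partners of primary reads.
#' @return An object of class `read_class_params`.
#' @export
read_class_params <- function(class_label = c("vsiRNA", "vpiRNA_primary",
                                              "vpiRNA_secondary",
                                              "degradation", "background"),
                              count,
                              length_dist = NULL,
                              strand_fraction_positive = 0.5,
                              positional_weights = NULL,
                              p_1U = NA_real_,
                              pingpong_fraction = 0) {
  class_label <- match.arg(class_label)
  count <- as.integer(count)
  if (is.na(count) || count < 0L) stop("count must be a non-negative integer")
  if (is.null(length_dist)) length_dist <- default_length_dist(class_label)
  length_dist <- normalize_length_dist(length_dist)
  stopifnot(strand_fraction_positive >= 0, strand_fraction_positive <= 1,
            pingpong_fraction >= 0, pingpong_fraction <= 1)
  if (!is.na(p_1U) && (p_1U < 0 || p_1U > 1)) stop("p_1U must be in [0,1]")
  structure(list(class_label = class_label, count = count,
                 length_dist = length_dist,
                 strand_fraction_positive = strand_fraction_positive,
                 positional_weights = positional_weights,
                 p_1U = p_1U, pingpong_fraction = pingpong_fraction),
            class = "read_class_params")
}

default_length_dist <- function(class_label) {
  d <- stats::setNames(numeric(15), 19:33)
  switch(class_label,
    vsiRNA = { d["21"] <- 1 },
    vpiRNA_primary = ,
    vpiRNA_secondary = ,
    degradation = { d[as.character(26:30)] <- 1 / 5 },
    background = {
      # 21-22 nt siRNA/miRNA-like peak plus a 27-30 nt piRNA-like shoulder
      d[c("21", "22")] <- c(0.30, 0.25)
      d[as.character(27:30)] <- 0.45 / 4
    })
  d
}

normalize_length_dist <- function(length_dist) {
  if (is.null(names(length_dist))) {
    stop("length_dist must be named by read length (19-33)")
  }
  lens <- as.integer(names(length_dist))
  if (any(is.na(lens)) || any(lens < 19L) || any(lens > 33L)) {
    stop("length_dist names must be lengths within 19-33")
  }
  if (any(length_dist < 0) || abs(sum(length_dist) - 1) > 1e-6) {
    stop("length_dist must be non-negative and sum to 1")
  }
  d <- stats::setNames(numeric(15), 19:33)
  d[as.character(lens)] <- length_dist
  d / sum(d)
}

# Draw n 5'-end positions (0-based) for reads of one (strand, length) group.
# want_u constrains the genomic base under the 5' end: TRUE = must be U/T in
# read space, FALSE = must not be, NA = unconstrained.
sample_five_prime <- function(n, genome_chars, weights, strand, len, want_u = NA) {
  G <- length(genome_chars)
  if (G < len) stop("genome shorter than requested read length")
  pos0 <- if (strand == "+") 0:(G - len) else (len - 1L):(G - 1L)
  w <- weights[pos0 + 1L]
  if (!is.na(want_u)) {
    base5 <- genome_chars[pos0 + 1L]
    is_u <- if (strand == "+") base5 == "T" else base5 == "A"
    w <- w * (if (want_u) is_u else !is_u)
  }
  if (sum(w) <= 0) stop("no genomic position satisfies the 5'-end constraint")
  pos0[sample.int(length(pos0), n, replace = TRUE, prob = w)]
}

#' Simulate one class of small RNA reads from a genome
#'
#' Draws read lengths, strands and 5'-end positions per the class parameters
#' and extracts the corresponding genomic windows. Negative-strand reads are
#' returned as the reverse complement of their genomic window; `strand`
#' always refers to the deposited reference orientation.
#'
#' For `vpiRNA_secondary` with `pingpong_fraction > 0`, that fraction of
#' reads is generated as exact 10-nt 5'-overlap partners of reads drawn from
#' `primaries`: the partner sits on the opposite strand with its 5' end 9 nt
#' downstream of the template's 5' end, so its 10th nucleotide is the
#' complement of the template's first (A when the template starts with U).
#'
#' @param genome Reference sequence (single character string over ACGT).
#' @param params A [read_class_params()].
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @param primaries Optional `data.frame` of previously simulated
#'   `vpiRNA_primary` reads (as returned by this function), required when
#'   `pingpong_fraction > 0`.
#' @return `data.frame` with columns `sequence` (read space, i.e. as
#'   sequenced), `strand` (`"+"`/`"-"`), `start` (0-based leftmost reference
#'   coordinate of the placement), `length`, `class_label`.
#' @export
simulate_class <- function(genome, params, seed, primaries = NULL) {
  stopifnot(inherits(params, "read_class_params"),
            is.character(genome), length(genome) == 1L)
  G <- nchar(genome)
  n <- params$count
  empty <- data.frame(sequence = character(0), strand = character(0),
                      start = integer(0), length = integer(0),
                      class_label = character(0))
  if (n == 0L) return(empty)
  min_len <- min(as.integer(names(params$length_dist)[params$length_dist > 0]))
  if (G < min_len) stop("genome shorter than the minimum read length of the class")
  w <- params$positional_weights %||% rep(1, G)
  if (length(w) != G) stop("positional_weights length must equal genome length")
  gch <- strsplit(genome, "", fixed = TRUE)[[1]]

  withr::with_seed(seed, {
    lens <- as.integer(sample(names(params$length_dist), n, replace = TRUE,
                              prob = params$length_dist))
    is_partner <- rep(FALSE, n)
    if (params$class_label == "vpiRNA_secondary" && params$pingpong_fraction > 0) {
      if (is.null(primaries) || nrow(primaries) == 0L) {
        stop("pingpong_fraction > 0 requires a non-empty 'primaries' table")
      }
      is_partner <- stats::runif(n) < params$pingpong_fraction
    }
    strand <- ifelse(stats::runif(n) < params$strand_fraction_positive, "+", "-")
    five0 <- integer(n)

    # ordinary (non-partner) reads, grouped by strand x length x 1U-constraint
    want_u <- rep(NA, n)
    if (params$class_label == "vpiRNA_primary" && !is.na(params$p_1U)) {
      want_u <- stats::runif(n) < params$p_1U
    }
    ord <- which(!is_partner)
    if (length(ord)) {
      grp <- split(ord, list(strand[ord], lens[ord], factor(want_u[ord], exclude = NULL)),
                   drop = TRUE)
      for (idx in grp) {
        five0[idx] <- sample_five_prime(length(idx), gch, w,
                                        strand[idx[1]], lens[idx[1]],
                                        want_u[idx[1]])
      }
    }

    # ping-pong partners: opposite strand, 5' ends overlapping by exactly 10 nt
    par <- which(is_partner)
    for (i in par) {
      repeat {
        tmpl <- primaries[sample.int(nrow(primaries), 1L), ]
        t5 <- if (tmpl$strand == "+") tmpl$start else tmpl$start + tmpl$length - 1L
        if (tmpl$strand == "+") {
          q <- t5 + 9L                       # partner on '-' strand, 5' at q
          if (q <= G - 1L && q - lens[i] + 1L >= 0L) {
            strand[i] <- "-"; five0[i] <- q; break
          }
        } else {
          p <- t5 - 9L                       # partner on '+' strand, 5' at p
          if (p >= 0L && p + lens[i] <= G) {
            strand[i] <- "+"; five0[i] <- p; break
          }
        }
      }
    }

    start0 <- ifelse(strand == "+", five0, five0 - lens + 1L)
    insert <- substring(genome, start0 + 1L, start0 + lens)
    seqs <- insert
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(insert[neg])
    data.frame(sequence = seqs, strand = strand, start = as.integer(start0),
               length = lens, class_label = params$class_label)
  })
}

#' Assemble a library recipe
#'
#' A recipe fully determines one simulated library: the genomes, the read
#' classes drawn from each (or from an independent host decoy sequence), the
#' per-base substitution error rate, the 3' adapter, the constant Phred
#' quality of emitted bases, and the master seed.
#'
#' @param genomes List of [genome_spec()] objects.
#' @param classes List of entries, each a list with elements `genome` (a
#'   genome name or `"host"`) and `params` (a [read_class_params()]).
#' @param sequencing_error_rate Per-base substitution probability in `[0,1]`.
#' @param adapter 3' adapter sequence appended to every insert (may be `""`).
#' @param constant_quality Phred score written for every base.
#' @param seed Master integer seed.
#' @param host_length Length of the independently generated host decoy
#'   sequence that `"host"` classes are drawn from.
#' @return Object of class `library_recipe`.
#' @export
library_recipe <- function(genomes, classes, sequencing_error_rate = 0,
                           adapter = "AGATCGGAAGAGC", constant_quality = 37,
                           seed = 1L, host_length = 10000L) {
  stopifnot(all(vapply(genomes, inherits, logical(1), "genome_spec")))
  names(genomes) <- vapply(genomes, `[[`, character(1), "name")
  if (anyDuplicated(names(genomes))) stop("genome names must be unique")
  if (sequencing_error_rate < 0 || sequencing_error_rate > 1) {
    stop("sequencing_error_rate must be in [0,1]")
  }
  for (cl in classes) {
    if (!is.list(cl) || !all(c("genome", "params") %in% names(cl))) {
      stop("each class entry must be list(genome=, params=)")
    }
    if (!cl$genome %in% c(names(genomes), "host")) {
      stop("class references undeclared genome: ", cl$genome)
    }
    stopifnot(inherits(cl$params, "read_class_params"))
  }
  structure(list(genomes = genomes, classes = classes,
                 sequencing_error_rate = sequencing_error_rate,
                 adapter = adapter,
                 constant_quality = as.integer(constant_quality),
                 seed = as.integer(seed),
                 host_length = as.integer(host_length)),
            class = "library_recipe")
}

#' Simulate all reads of a recipe
#'
#' Generates every genome (plus the host decoy), simulates each read class in
#' recipe order (primary piRNA classes feed ping-pong partners of secondary
#' classes on the same genome), and tallies a truth table of realized class
#' statistics. No sequencing errors or adapters are applied here; see
#' [emit_fastq()].
#'
#' @param recipe A [library_recipe()].
#' @return List with elements `reads` (data.frame: `genome`, `class_label`,
#'   `sequence`, `strand`, `start`, `length`), `sequences` (named character
#'   vector of genome sequences incl. `"host"`), and `truth` (data.frame, see
#'   [truth_table()]).
#' @export
simulate_library <- function(recipe) {
  stopifnot(inherits(recipe, "library_recipe"))
  seqs <- vapply(seq_along(recipe$genomes), function(k) {
    generate_genome(recipe$genomes[[k]], seed = recipe$seed + 101L * k)
  }, character(1))
  names(seqs) <- names(recipe$genomes)
  host_spec <- genome_spec("host", recipe$host_length)
  seqs <- c(seqs, host = generate_genome(host_spec, seed = recipe$seed + 99991L))

  reads <- vector("list", length(recipe$classes))
  primaries_by_genome <- list()
  for (k in seq_along(recipe$classes)) {
    cl <- recipe$classes[[k]]
    prim <- primaries_by_genome[[cl$genome]]
    df <- simulate_class(seqs[[cl$genome]], cl$params,
                         seed = recipe$seed + 7919L * k,
                         primaries = prim)
    if (nrow(df)) df$genome <- cl$genome else df$genome <- character(0)
    if (cl$params$class_label == "vpiRNA_primary") {
      primaries_by_genome[[cl$genome]] <-
        rbind(primaries_by_genome[[cl$genome]], df[setdiff(names(df), "genome")])
    }
    reads[[k]] <- df
  }
  reads <- do.call(rbind, reads)
  if (is.null(reads)) {
    reads <- data.frame(sequence = character(0), strand = character(0),
                        start = integer(0), length = integer(0),
                        class_label = character(0), genome = character(0))
  }
  list(reads = reads, sequences = seqs, truth = truth_table(reads))
}

#' Truth table of realized class statistics
#'
#' Per (genome, class): emitted read count, realized 1U frequency (5' base is
#' U), realized 10A frequency (A at read position 10, among reads of length
#' >= 10), and realized positive-strand fraction. Computed on the error-free
#' inserts.
#'
#' @param reads Read table from [simulate_library()].
#' @return `data.frame` with one row per (genome, class_label).
#' @export
truth_table <- function(reads) {
  if (nrow(reads) == 0L) {
    return(data.frame(genome = character(0), class_label = character(0),
                      count = integer(0), freq_1U = numeric(0),
                      freq_10A = numeric(0), strand_fraction_positive = numeric(0)))
  }
  key <- interaction(reads$genome, reads$class_label, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(reads)), key), function(i) {
    r <- reads[i, ]
    has10 <- r$length >= 10L
    data.frame(genome = r$genome[1], class_label = r$class_label[1],
               count = nrow(r),
               freq_1U = mean(substr(r$sequence, 1L, 1L) == "T"),
               freq_10A = if (any(has10))
                 mean(substr(r$sequence[has10], 10L, 10L) == "A") else NA_real_,
               strand_fraction_positive = mean(r$strand == "+"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emit a simulated library as FASTQ
#'
#' Applies per-base substitution errors to each insert, appends the 3'
#' adapter, attaches a constant-quality string, shuffles read order
#' deterministically under the recipe seed, and writes Phred+33 FASTQ. The
#' truth table is written beside the FASTQ as TSV.
#'
#' @param sim Result of [simulate_library()].
#' @param recipe The [library_recipe()] used to build `sim`.
#' @param path Output FASTQ path (`.gz` supported).
#' @return Invisibly, a list with `truth` (aggregate truth table), `reads`
#'   (per-read table incl. `id` and `n_errors`, in emitted order), and
#'   `path`.
#' @export
emit_fastq <- function(sim, recipe, path) {
  stopifnot(inherits(recipe, "library_recipe"))
  reads <- sim$reads
  n <- nrow(reads)
  withr::with_seed(recipe$seed + 424243L, {
    ord <- if (n > 0L) sample.int(n) else integer(0)
    reads <- reads[ord, , drop = FALSE]
    seqs <- reads$sequence
    n_errors <- integer(n)
    if (recipe$sequencing_error_rate > 0 && n > 0L) {
      for (i in seq_len(n)) {
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(length(ch)) < recipe$sequencing_error_rate)
        for (j in hit) ch[j] <- sample(setdiff(BASES, ch[j]), 1L)
        if (length(hit)) seqs[i] <- paste0(ch, collapse = "")
        n_errors[i] <- length(hit)
      }
    }
    ids <- sprintf("sim%06d", seq_len(n))
    if (n > 0L) {
      out_seqs <- paste0(seqs, recipe$adapter)
      qchar <- rawToChar(as.raw(recipe$constant_quality + 33L))
      dna <- Biostrings::DNAStringSet(out_seqs)
      names(dna) <- ids
      qual <- Biostrings::BStringSet(strrep(qchar, nchar(out_seqs)))
      Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
    } else {
      writeLines(character(0), path)   # valid empty FASTQ
    }
    if (n > 0L) {
      reads$id <- ids
      reads$n_errors <- n_errors
    } else {
      reads$id <- character(0)
      reads$n_errors <- integer(0)
    }
  })
  truth <- sim$truth
  write_tsv(truth, paste0(path, ".truth.tsv"))
  invisible(list(truth = truth, reads = reads, path = path))
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ path, plain or gzip.
#' @return List with `id` (character), `sequence` (character), `quality`
#'   (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns when dropping its own metadata cols
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  quals <- methods::as(Biostrings::quality(x), "IntegerList")
  list(id = names(x) %||% character(0),
       sequence = unname(as.character(x)),
       quality = unname(as.list(quals)))
}
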