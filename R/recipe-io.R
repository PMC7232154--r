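# YAML recipe files.
#
# Schema (all keys at top level unless nested):
#   seed: 1
#   sequencing_error_rate: 0.0
#   adapter: AGATCGGAAGAGC
#   constant_quality: 37
#   host_length: 10000
#   genomes:
#     - name: MERV
#       length: 11004
#       sense: negative
#       base_composition: {A: 0.25, C: 0.25, G: 0.25, T: 0.25}   # optional
#       genes:                                                   # optional
#         - {label: N, start: 130, end: 1500}
#   classes:
#     - genome: MERV            # or "host"
#       class_label: vpiRNA_primary
#       count: 5000
#       strand_fraction_positive: 1.0
#       p_1U: 0.9               # vpiRNA_primary only
#       pingpong_fraction: 0.5  # vpiRNA_secondary only
#       length_dist: {26: 0.2, 27: 0.2, 28: 0.2, 29: 0.2, 30: 0.2}  # optional
#       hotspots:               # optional; multiplies uniform weights
#         - {start: 0, end: 130, weight: 10}

#' Read a library recipe from YAML
#'
#' Hotspot entries (`start`, `end`, `weight`; 0-based half-open) are expanded
#' into per-position sampling weights over the genome, uniform elsewhere.
#'
#' @param path YAML recipe path.
#' @return A [library_recipe()].
#' @export
read_recipe <- function(path) {
  y <- yaml::read_yaml(path)
  genomes <- lapply(y$genomes, function(g) {
    comp <- if (!is.null(g$base_composition)) {
      unlist(g$base_composition)[BASES]
    } else c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    genes <- if (!is.null(g$genes)) {
      do.call(rbind, lapply(g$genes, function(x) {
        data.frame(label = x$label, start = x$start, end = x$end)
      }))
    } else NULL
    genome_spec(g$name, g$length, sense = g$sense %||% "positive",
                genes = genes, base_composition = comp)
  })
  names(genomes) <- vapply(genomes, `[[`, character(1), "name")
  glen <- vapply(genomes, `[[`, integer(1), "length")
  host_length <- as.integer(y$host_length %||% 10000L)

  classes <- lapply(y$classes, function(cl) {
    gname <- cl$genome
    G <- if (identical(gname, "host")) host_length else glen[[gname]]
    weights <- NULL
    if (!is.null(cl$hotspots)) {
      weights <- rep(1, G)
      for (h in cl$hotspots) {
        weights[(h$start + 1L):h$end] <- h$weight
      }
    }
    ld <- if (!is.null(cl$length_dist)) unlist(cl$length_dist) else NULL
    list(genome = gname,
         params = read_class_params(
           class_label = cl$class_label,
           count = cl$count,
           length_dist = ld,
           strand_fraction_positive = cl$strand_fraction_positive %||% 0.5,
           positional_weights = weights,
           p_1U = cl$p_1U %||% NA_real_,
           pingpong_fraction = cl$pingpong_fraction %||% 0))
  })
  library_recipe(genomes = genomes, classes = classes,
                 sequencing_error_rate = y$sequencing_error_rate %||% 0,
                 adapter = y$adapter %||% "AGATCGGAAGAGC",
                 constant_quality = y$constant_quality %||% 37L,
                 seed = y$seed %||% 1L,
                 host_length = host_length)
}
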