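# Library simulator: genome generation, class sampling, FASTQ emission.

test_that("generate_genome honors length, composition and determinism", {
  # degenerate composition
  g <- generate_genome(genome_spec("a", 10, base_composition = c(A = 1, C = 0, G = 0, T = 0)), 1)
  expect_identical(g, "AAAAAAAAAA")

  # uniform composition at the AEFV genome length: each base within a
  # 3-sigma binomial band around 0.25
  g2 <- generate_genome(genome_spec("u", 11064), 1)
  p <- table(strsplit(g2, "")[[1]]) / 11064
  tol <- 3 * sqrt(0.25 * 0.75 / 11064)
  expect_true(all(abs(p - 0.25) < tol))

  # determinism
  expect_identical(generate_genome(genome_spec("u", 500), 42),
                   generate_genome(genome_spec("u", 500), 42))

  expect_error(genome_spec("bad", 100, base_composition = c(A = 0.5, C = 0.5, G = 0.5, T = 0.5)),
               "base_composition")
  expect_error(genome_spec("bad", 0), "positive")
})

test_that("gene intervals are validated and round-trip through BED", {
  genes <- data.frame(label = c("5UTR", "N"), start = c(0L, 130L),
                      end = c(130L, 1500L))
  gs <- genome_spec("MERV", 2000, sense = "negative", genes = genes)
  path <- tempfile(fileext = ".bed")
  write_gene_bed(gs, path)
  back <- read_gene_bed(path)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$label, genes$label)
  expect_error(genome_spec("x", 100, genes = data.frame(label = "g", start = 50, end = 40)),
               "gene intervals")
})

test_that("forced 1U makes every primary read start with U", {
  g <- random_genome(3000, 7)
  params <- read_class_params("vpiRNA_primary", 100,
                              strand_fraction_positive = 1, p_1U = 1.0)
  reads <- simulate_class(g, params, seed = 3)
  expect_equal(nrow(reads), 100)
  expect_true(all(substr(reads$sequence, 1, 1) == "T"))
})

test_that("ping-pong partners of 1U primaries carry a forced 10A", {
  g <- random_genome(3000, 8)
  prim <- simulate_class(g, read_class_params("vpiRNA_primary", 200,
                                              strand_fraction_positive = 1,
                                              p_1U = 1.0), seed = 4)
  sec <- simulate_class(g, read_class_params("vpiRNA_secondary", 200,
                                             pingpong_fraction = 1.0),
                        seed = 5, primaries = prim)
  expect_true(all(sec$strand == "-"))
  expect_true(all(substr(sec$sequence, 10, 10) == "A"))
  # and the 5' ends overlap the template set by exactly 10 nt
  prim5 <- prim$start                                   # + strand: leftmost
  sec5 <- sec$start + sec$length - 1L                   # - strand: rightmost
  expect_true(all(sec5 %in% (prim5 + 9L)))
})

test_that("sampled 1U frequency converges to p_1U (binomial 3-sigma band)", {
  g <- random_genome(5000, 21)
  reads <- simulate_class(g, read_class_params("vpiRNA_primary", 10000,
                                               strand_fraction_positive = 1,
                                               p_1U = 0.9), seed = 7)
  f <- mean(substr(reads$sequence, 1, 1) == "T")
  tol <- 3 * sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(f - 0.9), tol)
})

test_that("class simulation rejects genomes shorter than the read length", {
  expect_error(simulate_class(strrep("A", 10),
                              read_class_params("vsiRNA", 5), seed = 1),
               "shorter")
})

test_that("simulated reads are exact genomic windows when error rate is 0", {
  gs <- genome_spec("V", 2500)
  classes <- list(
    list(genome = "V", params = read_class_params("vsiRNA", 300)),
    list(genome = "V", params = read_class_params("vpiRNA_primary", 200,
                                                  strand_fraction_positive = 1,
                                                  p_1U = 0.9)),
    list(genome = "V", params = read_class_params("vpiRNA_secondary", 150,
                                                  pingpong_fraction = 0.7)),
    list(genome = "V", params = read_class_params("degradation", 150,
                                                  strand_fraction_positive = 0.8)),
    list(genome = "host", params = read_class_params("background", 100)))
  rec <- library_recipe(list(gs), classes, sequencing_error_rate = 0, seed = 5)
  sim <- simulate_library(rec)
  for (i in seq_len(nrow(sim$reads))) {
    r <- sim$reads[i, ]
    window <- substr(sim$sequences[[r$genome]], r$start + 1, r$start + r$length)
    expected <- if (r$strand == "+") window else revcomp(window)
    expect_identical(r$sequence, expected)
  }
})

test_that("truth table counts equal requested counts and cover all classes", {
  gs <- genome_spec("V", 1200)
  classes <- list(
    list(genome = "V", params = read_class_params("vsiRNA", 111)),
    list(genome = "host", params = read_class_params("background", 57)))
  rec <- library_recipe(list(gs), classes, seed = 2)
  sim <- simulate_library(rec)
  tt <- sim$truth
  expect_setequal(tt$count, c(111L, 57L))
  expect_equal(sum(tt$count), nrow(sim$reads))
})

test_that("FASTQ emission: concatenation, empty library, determinism", {
  gs <- genome_spec("V", 600)
  rec1 <- library_recipe(list(gs),
                         list(list(genome = "V",
                                   params = read_class_params("vsiRNA", 1))),
                         adapter = "AGATCGGAAGAGC", seed = 3)
  f1 <- tempfile(fileext = ".fastq")
  emit_fastq(simulate_library(rec1), rec1, f1)
  fq <- read_fastq(f1)
  expect_equal(nchar(fq$sequence), 21 + 13)       # insert + adapter
  expect_equal(length(fq$quality[[1]]), 34)

  # empty library -> valid empty FASTQ, zero-count truth
  rec0 <- library_recipe(list(gs), list(), seed = 3)
  f0 <- tempfile(fileext = ".fastq")
  out0 <- emit_fastq(simulate_library(rec0), rec0, f0)
  expect_equal(nrow(out0$truth), 0)
  expect_equal(length(read_fastq(f0)$sequence), 0)

  # byte-identical re-emission under the same seed
  recd <- library_recipe(list(gs),
                         list(list(genome = "V",
                                   params = read_class_params("vsiRNA", 40))),
                         sequencing_error_rate = 0.01, seed = 3)
  fa <- tempfile(fileext = ".fastq"); fb <- tempfile(fileext = ".fastq")
  emit_fastq(simulate_library(recd), recd, fa)
  emit_fastq(simulate_library(recd), recd, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("degradation reads reproduce genome base composition (chi-square)", {
  g <- random_genome(2000, 33)
  reads <- simulate_class(g, read_class_params("degradation", 4000,
                                               strand_fraction_positive = 1),
                          seed = 9)
  # pooled base counts over the first 26 read positions vs genome composition
  comp <- table(factor(strsplit(g, "")[[1]], levels = c("A", "C", "G", "T")))
  pooled <- table(factor(unlist(strsplit(substr(reads$sequence, 1, 26), "")),
                         levels = c("A", "C", "G", "T")))
  p <- stats::chisq.test(pooled, p = as.numeric(comp) / sum(comp))$p.value
  expect_gt(p, 0.01)
})

test_that("YAML recipes round-trip into working simulations with hotspots", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 11",
    "sequencing_error_rate: 0.0",
    "adapter: AGATCGGAAGAGC",
    "genomes:",
    "  - name: MERV",
    "    length: 2000",
    "    sense: negative",
    "classes:",
    "  - genome: MERV",
    "    class_label: vsiRNA",
    "    count: 500",
    "    strand_fraction_positive: 0.3",
    "    hotspots:",
    "      - {start: 100, end: 200, weight: 25}",
    "  - genome: host",
    "    class_label: background",
    "    count: 100"), yml)
  rec <- read_recipe(yml)
  expect_s3_class(rec, "library_recipe")
  sim <- simulate_library(rec)
  expect_equal(nrow(sim$reads), 600)
  # hotspot weighting concentrates 5' ends in [100, 200)
  vs <- sim$reads[sim$reads$class_label == "vsiRNA", ]
  five0 <- ifelse(vs$strand == "+", vs$start, vs$start + vs$length - 1L)
  inside <- mean(five0 >= 100 & five0 < 200)
  # 100/2000 of positions carry 25x weight -> expected share 25*100/(25*100+1900)
  expect_gt(inside, 0.4)
})
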