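# Pigeonhole seed index and one-mismatch alignment.

test_that("seed index lookups enumerate exact positions deterministically", {
  idx <- build_index("ACGTACGT", name = "toy", seed_len = 4)
  expect_identical(index_lookup(idx, "ACGT"), c(0L, 4L))
  expect_identical(index_lookup(idx, "CGTA"), 1L)
  expect_identical(index_lookup(idx, "TTTT"), integer(0))

  idx2 <- build_index("ACGTACGT", name = "toy", seed_len = 4)
  expect_identical(ls(idx$table), ls(idx2$table))

  # every 9-mer of a random 2 kb reference is found at all its positions
  ref <- random_genome(2000, 61)
  idx9 <- build_index(ref)
  for (s in c(0L, 1L, 997L, 1990L, 1991L)) {
    seed <- substr(ref, s + 1, s + 9)
    expect_true(s %in% index_lookup(idx9, seed))
  }
  # exhaustive: lookups of all distinct 9-mers recover every position once
  all_starts <- sort(unlist(lapply(
    unique(substring(ref, 1:1992, 9:2000)),
    function(k) index_lookup(idx9, k))))
  expect_identical(all_starts, 0:1991)

  expect_error(build_index(""), "empty")
})

test_that("exact placements are reported on both strands", {
  # this repetitive reference also carries reverse-complement copies, so the
  # stated loci are asserted via the candidate set
  ref <- "AAAACCCCGGGGTTTTAAAACCCCGGGG"
  idx <- build_index(ref, seed_len = 4)
  ca <- align_candidates("CCCCGGGGTTTT", idx)
  expect_true(any(ca$strand == "+" & ca$start == 4L & ca$mismatches == 0L))

  rc <- revcomp(substr(ref, 5, 16))          # reverse complement of [4,16)
  cb <- align_candidates(rc, idx)
  expect_true(any(cb$strand == "-" & cb$start == 4L & cb$mismatches == 0L))
  # every reported candidate is exact under brute force
  expect_equal(sort_candidates(ca), sort_candidates(oracle_candidates("CCCCGGGGTTTT", ref)))

  # unique placements on a non-repetitive reference come back single-hit
  g <- random_genome(1000, 3)
  idx9 <- build_index(g, name = "g")
  a <- align_read(substr(g, 101, 121), idx9)
  expect_identical(a$strand, "+")
  expect_identical(a$start, 100L)
  expect_identical(a$mismatches, 0L)
  b <- align_read(revcomp(substr(g, 101, 126)), idx9)
  expect_identical(b$strand, "-")
  expect_identical(b$start, 100L)
})

test_that("candidate sets match the brute-force scan on random references", {
  withr::with_seed(606, {
    ref <- random_genome(1500, 71)
    idx <- build_index(ref)
    for (i in 1:150) {
      L <- sample(19:33, 1)
      type <- sample(c("planted0", "planted1", "decoy"), 1)
      s0 <- sample.int(1500 - L, 1)
      read <- substr(ref, s0, s0 + L - 1)
      if (type == "planted1") read <- substitute_base(read, sample.int(L, 1))
      if (type == "decoy") read <- paste0(sample(c("A", "C", "G", "T"), L, TRUE),
                                          collapse = "")
      if (sample(c(TRUE, FALSE), 1)) read <- revcomp(read)
      got <- sort_candidates(align_candidates(read, idx))
      want <- sort_candidates(oracle_candidates(read, ref))
      expect_equal(got, want)
    }
  })
})

test_that("candidate starts agree with Biostrings::matchPattern", {
  withr::with_seed(609, {
    ref <- random_genome(2500, 72)
    subject <- Biostrings::DNAString(ref)
    idx <- build_index(ref)
    for (i in 1:30) {
      L <- sample(19:33, 1)
      s0 <- sample.int(2500 - L, 1)
      read <- substr(ref, s0, s0 + L - 1)
      if (i %% 3 == 0) read <- substitute_base(read, sample.int(L, 1))
      cand <- align_candidates(read, idx)
      plus <- sort(cand$start[cand$strand == "+"])
      hits <- Biostrings::matchPattern(read, subject, max.mismatch = 1)
      expect_identical(plus, sort(Biostrings::start(hits) - 1L))
      minus <- sort(cand$start[cand$strand == "-"])
      rhits <- Biostrings::matchPattern(revcomp(read), subject, max.mismatch = 1)
      expect_identical(minus, sort(Biostrings::start(rhits) - 1L))
    }
  })
})

test_that("every planted read with at most one mismatch maps", {
  withr::with_seed(607, {
    ref <- random_genome(3000, 81)
    idx <- build_index(ref)
    for (i in 1:100) {
      L <- sample(19:33, 1)
      s0 <- sample.int(3000 - L, 1)
      read <- substr(ref, s0, s0 + L - 1)
      if (i %% 2 == 0) read <- substitute_base(read, sample.int(L, 1))
      expect_false(is.null(align_read(read, idx)))
    }
  })
})

test_that("strand mirror: aligning the reverse complement flips the strand", {
  withr::with_seed(608, {
    ref <- random_genome(2000, 91)
    idx <- build_index(ref)
    checked <- 0
    for (i in 1:60) {
      L <- sample(19:33, 1)
      s0 <- sample.int(2000 - L, 1)
      read <- substr(ref, s0, s0 + L - 1)
      cand <- align_candidates(read, idx)
      if (nrow(cand) != 1L) next                    # only uniquely mapping reads
      mirror <- align_candidates(revcomp(read), idx)
      expect_equal(nrow(mirror), 1L)
      expect_identical(mirror$start, cand$start)
      expect_true(mirror$strand != cand$strand)
      checked <- checked + 1
    }
    expect_gt(checked, 30)
  })
})

test_that("library alignment is deterministic under a fixed seed", {
  base <- random_genome(800, 101)
  ref <- paste0(base, substr(base, 1, 200))   # duplicated block -> tied placements
  idx <- list(V = build_index(ref, name = "V"))
  reads <- withr::with_seed(11, {
    vapply(1:60, function(i) {
      paste0(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    }, character(1))
  })
  # reads from the duplicated block map to two tied loci
  reads <- c(reads, substring(base, c(11, 40, 90), c(31, 60, 110)))
  ids <- sprintf("r%02d", seq_along(reads))
  a1 <- align_library(ids, reads, idx, library_total = length(reads), seed = 5)
  a2 <- align_library(ids, reads, idx, library_total = length(reads), seed = 5)
  expect_identical(a1$records, a2$records)
  expect_error(align_library(ids, reads, idx, library_total = 0, seed = 5),
               "library_total")
})

test_that("an all-host library maps nowhere; N counts as a mismatch", {
  host <- random_genome(2000, 111)
  virus <- random_genome(2000, 112)
  idx <- list(V = build_index(virus, name = "V"))
  withr::with_seed(12, {
    starts <- sample.int(2000 - 25, 40)
  })
  reads <- substring(host, starts, starts + 24)
  aln <- align_library(sprintf("h%02d", 1:40), reads, idx,
                       library_total = 40, seed = 9)
  expect_equal(nrow(aln$records$V), 0)
  expect_equal(unname(aln$unmapped["V"]), 40)

  # a read matching exactly except for one N maps with 1 mismatch;
  # with two N it does not map
  w <- substr(virus, 101, 121)
  one_n <- paste0(substr(w, 1, 10), "N", substr(w, 12, 21))
  two_n <- paste0("N", substr(w, 2, 10), "N", substr(w, 12, 21))
  expect_identical(align_read(one_n, idx$V)$mismatches, 1L)
  expect_null(align_read(two_n, idx$V))
})

test_that("SAM output uses 1-based POS, FLAG 16 and NM, and round-trips", {
  ref <- random_genome(500, 121)
  idx <- list(V = build_index(ref, name = "V"))
  reads <- c(substr(ref, 1, 21),                     # + strand at start 0
             revcomp(substr(ref, 5, 30)))            # - strand at start 4
  aln <- align_library(c("p", "m"), reads, idx, library_total = 2, seed = 1)
  path <- tempfile(fileext = ".sam")
  write_sam(aln, idx, path)
  lines <- readLines(path)
  expect_true(any(grepl("^@SQ\tSN:V\tLN:500$", lines)))
  body <- lines[!startsWith(lines, "@")]
  fp <- strsplit(body[1], "\t")[[1]]
  fm <- strsplit(body[2], "\t")[[1]]
  expect_identical(fp[c(2, 4)], c("0", "1"))         # FLAG 0, POS 1
  expect_identical(fm[c(2, 4)], c("16", "5"))        # FLAG 16, POS 5
  expect_identical(fm[10], substr(ref, 5, 30))       # SEQ reference-forward

  back <- read_sam(path)
  rec <- aln$records$V
  expect_identical(back$read_id, rec$read_id)
  expect_identical(back$strand, rec$strand)
  expect_identical(back$start, rec$start)
  expect_identical(back$mismatches, rec$mismatches)
  expect_identical(back$sequence, rec$sequence)
})
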