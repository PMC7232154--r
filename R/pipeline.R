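# End-to-end orchestration: trim -> align -> profile -> signature, with a
# consolidated per-library report and cross-library comparison.

#' Validate and normalize a pipeline run configuration
#'
#' A configuration may be given as a YAML file path or a list with elements:
#' `libraries` (list of `list(path=, label=)`), `references` (FASTA path),
#' `annotations` (optional BED path), `adapter`, `quality_cutoff`,
#' `min_len`, `max_len`, `pirna_window` (two integers, default `c(26, 30)`;
#' 26-32 accommodates broader piRNA definitions), `seed`, `outdir`.
#'
#' @param config YAML path or list.
#' @return Validated list of class `run_config` with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$libraries),
            !is.null(config$references), !is.null(config$outdir))
  for (lib in config$libraries) {
    if (!file.exists(lib$path)) stop("FASTQ not found: ", lib$path)
  }
  if (!file.exists(config$references)) {
    stop("reference FASTA not found: ", config$references)
  }
  if (!is.null(config$annotations) && !file.exists(config$annotations)) {
    stop("annotation BED not found: ", config$annotations)
  }
  defaults <- list(adapter = "AGATCGGAAGAGC", quality_cutoff = 20L,
                   min_len = 19L, max_len = 33L, pirna_window = c(26L, 30L),
                   seed = 1L)
  for (nm in names(defaults)) {
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  }
  structure(config, class = c("run_config", "list"))
}

#' Run the full small RNA profiling pipeline
#'
#' For each library: trim (adapter, quality, length window), align to every
#' viral reference with at most one mismatch, then compute the size
#' distribution, per-virus 21 nt and piRNA-window counts, RPM values, the
#' vpiRNA:vsiRNA ratio, 5'-end coverage profiles with hotspot flags,
#' positional nucleotide frequency matrices per strand, 1U/10A bias tests
#' (1U on `+`, 10A on `-`, plus the reciprocal assignment), and the
#' ping-pong overlap histogram. All intermediates are written as TSV (plus
#' SAM) under `outdir/<label>/` before downstream stages consume them, and
#' every reported number is recomputable from those files.
#'
#' @param config A [run_config()] (or YAML path / list coercible to one).
#' @return Object of class `run_report`: `config` echo, `libraries` (per
#'   library: `qc`, per-virus statistics) and `summary` (flat
#'   `data.frame`, one row per library x virus).
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  genomes <- read_genome_fasta(config$references)
  indexes <- lapply(names(genomes), function(nm) build_index(genomes[[nm]], nm))
  names(indexes) <- names(genomes)
  pirna_lens <- config$pirna_window[1]:config$pirna_window[2]
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  logf("virnaprof %s | seed %d | piRNA window %d-%d",
       as.character(utils::packageVersion("virnaprof")), config$seed,
       config$pirna_window[1], config$pirna_window[2])

  libraries <- list()
  rows <- list()
  for (lib in config$libraries) {
    label <- lib$label
    libdir <- file.path(config$outdir, label)
    dir.create(libdir, showWarnings = FALSE, recursive = TRUE)

    qc <- trim_fastq(lib$path, output = file.path(libdir, "trimmed.fastq"),
                     adapter = config$adapter,
                     quality_cutoff = config$quality_cutoff,
                     min_len = config$min_len, max_len = config$max_len)
    write_qc_report(qc, file.path(libdir, "qc.tsv"))
    logf("[%s] trim: %d in, %d kept", label, qc$reads_in, qc$reads_kept)
    write_tsv(size_distribution(qc$lengths,
                                config$min_len, config$max_len),
              file.path(libdir, "size_distribution.tsv"))

    per_virus <- list()
    if (qc$reads_kept > 0L) {
      aln <- align_library(qc$ids, qc$sequences, indexes,
                           library_total = qc$reads_kept, seed = config$seed)
      write_sam(aln, indexes, file.path(libdir, "alignments.sam"))
    } else {
      aln <- NULL
    }
    for (nm in names(indexes)) {
      rec <- if (is.null(aln)) data.frame(read_id = character(0),
                                          reference = character(0),
                                          strand = character(0),
                                          start = integer(0),
                                          read_length = integer(0),
                                          mismatches = integer(0),
                                          sequence = character(0))
             else aln$records[[nm]]
      G <- nchar(genomes[[nm]])
      n21 <- sum(rec$read_length == 21L)
      n_pi <- sum(rec$read_length %in% pirna_lens)
      ratio <- vpirna_vsirna_ratio(n_pi, n21, virus = nm, tissue = label)
      rpm21 <- if (qc$reads_kept > 0L) rpm_normalize(n21, qc$reads_kept) else
        structure(list(raw = 0L, library_total = 0L, value = 0),
                  class = "rpm_value")
      prof21 <- coverage_profile(rec, G, length_class = 21L)
      prof_pi <- coverage_profile(rec, G, length_class = pirna_lens)
      write_tsv(size_distribution(rec, config$min_len, config$max_len),
                file.path(libdir, sprintf("size_distribution_%s.tsv", nm)))
      write_coverage_tsv(prof21, file.path(libdir, sprintf("profile_%s_21.tsv", nm)))
      write_coverage_tsv(prof_pi,
                         file.path(libdir, sprintf("profile_%s_%d-%d.tsv", nm,
                                                   min(pirna_lens), max(pirna_lens))))
      hotspots <- hotspot_flags(prof21)
      bias <- list()
      pp <- pingpong_overlap(rec, length_class = pirna_lens)
      for (strand in c("+", "-")) {
        fm <- nucleotide_frequency_matrix(rec, strand, length_class = pirna_lens)
        sname <- if (strand == "+") "plus" else "minus"
        write_frequency_tsv(fm, file.path(libdir,
                                          sprintf("freq_matrix_%s_%s.tsv", nm, sname)))
        comp <- strand_base_composition(genomes[[nm]], strand)
        for (test in list(c(1L, "U"), c(10L, "A"))) {
          pos <- as.integer(test[1]); nt <- test[2]
          key <- sprintf("%d%s_%s", pos, nt, sname)
          bias[[key]] <- if (fm$coverage[pos] > 0L) {
            bias_test(fm, pos, nt, background = comp[[nt]])
          } else NULL
        }
      }
      write_tsv(data.frame(overlap = pp$overlap, count = pp$count),
                file.path(libdir, sprintf("pingpong_%s.tsv", nm)))
      per_virus[[nm]] <- list(mapped = nrow(rec), n21 = n21, n_pirna = n_pi,
                              ratio = ratio, rpm21 = rpm21,
                              hotspots = hotspots, bias = bias, pingpong = pp)
      rows[[paste(label, nm)]] <- data.frame(
        library = label, virus = nm,
        reads_kept = qc$reads_kept, mapped = nrow(rec),
        n21 = n21, n_pirna = n_pi,
        ratio_per_100 = ratio$value, rpm21 = rpm21$value,
        biased_1U_plus = !is.null(bias[["1U_plus"]]) && bias[["1U_plus"]]$biased,
        biased_10A_minus = !is.null(bias[["10A_minus"]]) && bias[["10A_minus"]]$biased,
        z10 = pp$z10, n_hotspots = nrow(hotspots))
      logf("[%s] %s: mapped %d, n21 %d, n%d-%d %d, ratio %s", label, nm,
           nrow(rec), n21, min(pirna_lens), max(pirna_lens), n_pi,
           ifelse(ratio$undefined, "undefined", sprintf("%.1f", ratio$value)))
    }
    libraries[[label]] <- list(qc = qc, per_virus = per_virus)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  write_tsv(summary, file.path(config$outdir, "report.tsv"))
  structure(list(config = config, libraries = libraries, summary = summary),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("virnaprof run report\n")
  print(x$summary)
  invisible(x)
}

#' Cross-library comparison of vsiRNA production
#'
#' Per virus, each library's share (%) of the summed 21 nt signal across
#' libraries. Shares are computed on RPM by default so libraries of
#' different depths are comparable; a raw-count mode is available.
#'
#' @param reports List of two or more [run_pipeline()] reports sharing a
#'   virus set.
#' @param metric `"rpm"` (default) or `"raw"`.
#' @return `data.frame`: `virus`, `library`, `value` (the metric), `share`
#'   (percent of the per-virus column sum).
#' @export
compare_libraries <- function(reports, metric = c("rpm", "raw")) {
  metric <- match.arg(metric)
  stopifnot(length(reports) >= 2L)
  tabs <- lapply(reports, function(r) {
    stopifnot(inherits(r, "run_report"))
    s <- r$summary
    data.frame(virus = s$virus, library = s$library,
               value = if (metric == "rpm") s$rpm21 else s$n21)
  })
  tab <- do.call(rbind, tabs)
  virus_sets <- lapply(tabs, function(t) sort(unique(t$virus)))
  shared <- Reduce(intersect, virus_sets)
  if (length(shared) == 0L) stop("reports share no viruses")
  tab <- tab[tab$virus %in% shared, , drop = FALSE]
  out <- do.call(rbind, lapply(split(tab, tab$virus), function(t) {
    t$share <- if (sum(t$value) > 0) 100 * t$value / sum(t$value) else NA_real_
    t
  }))
  rownames(out) <- NULL
  out
}
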