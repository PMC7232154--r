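# Size distributions, RPM normalization, strand-resolved 5'-end coverage,
# hotspot detection, and the vpiRNA:vsiRNA proportion statistic.

#' Strand-resolved read size distribution
#'
#' Counts reads per length over the 19-33 nt window. For mapped input (an
#' alignment record `data.frame`) counts are split by strand; for a plain
#' vector of read lengths (whole-library scope, where strand is undefined)
#' only the total column is filled.
#'
#' @param x Alignment record `data.frame` (columns `read_length`, `strand`)
#'   or an integer vector of read lengths.
#' @param min_len,max_len Length window (inclusive).
#' @return `data.frame` with columns `length`, `positive`, `negative`,
#'   `total`; total always sums to the number of input reads.
#' @export
size_distribution <- function(x, min_len = 19L, max_len = 33L) {
  lens <- min_len:max_len
  if (is.data.frame(x)) {
    stopifnot(all(c("read_length", "strand") %in% names(x)))
    if (nrow(x) && (any(x$read_length < min_len) || any(x$read_length > max_len))) {
      stop("read lengths outside the size window")
    }
    pos <- table(factor(x$read_length[x$strand == "+"], levels = lens))
    neg <- table(factor(x$read_length[x$strand == "-"], levels = lens))
    data.frame(length = lens,
               positive = as.integer(pos),
               negative = as.integer(neg),
               total = as.integer(pos) + as.integer(neg))
  } else {
    if (length(x) && (any(x < min_len) || any(x > max_len))) {
      stop("read lengths outside the size window")
    }
    tot <- table(factor(x, levels = lens))
    data.frame(length = lens,
               positive = NA_integer_, negative = NA_integer_,
               total = as.integer(tot))
  }
}

#' Reads-per-million normalization
#'
#' `value = 1e6 * raw / library_total`. The denominator is the number of
#' reads kept after trimming (configurable by passing a different total).
#'
#' @param raw Raw read count (non-negative).
#' @param library_total Library total (positive).
#' @return List of class `rpm_value` with `raw`, `library_total`, `value`.
#' @export
rpm_normalize <- function(raw, library_total) {
  if (library_total <= 0) stop("library_total must be positive")
  if (any(raw < 0)) stop("raw count must be non-negative")
  structure(list(raw = raw, library_total = library_total,
                 value = 1e6 * raw / library_total),
            class = "rpm_value")
}

#' Strand-resolved 5'-end coverage profile
#'
#' Counts read 5' ends per reference position for one length class. The 5'
#' end of a `+` strand placement is its leftmost reference position; for a
#' `-` strand placement it is the rightmost position (the biological 5'
#' terminus). One count per read, so the profile sums exactly to the number
#' of reads in the class. A per-base mode counts every covered position
#' instead (for plotting parity with full-coverage figures).
#'
#' @param alignments Alignment record `data.frame` for one reference.
#' @param genome_length Reference length (nt).
#' @param length_class Integer vector of read lengths included, e.g. `21`
#'   (vsiRNA) or `26:30` (vpiRNA candidates).
#' @param mode `"five_prime"` (default) or `"per_base"`.
#' @return `data.frame` of class `coverage_profile`: `position` (0-based),
#'   `positive`, `negative`; attributes `length_class`, `mode`, `n_reads`.
#' @export
coverage_profile <- function(alignments, genome_length,
                             length_class = 21L,
                             mode = c("five_prime", "per_base")) {
  mode <- match.arg(mode)
  sel <- alignments[alignments$read_length %in% length_class, , drop = FALSE]
  pos_counts <- numeric(genome_length)
  neg_counts <- numeric(genome_length)
  if (nrow(sel)) {
    if (any(sel$start < 0L) || any(sel$start + sel$read_length > genome_length)) {
      stop("alignment outside the reference; wrong genome_length or virus?")
    }
    if (mode == "five_prime") {
      five0 <- ifelse(sel$strand == "+", sel$start,
                      sel$start + sel$read_length - 1L)
      pos_counts <- tabulate(five0[sel$strand == "+"] + 1L, genome_length)
      neg_counts <- tabulate(five0[sel$strand == "-"] + 1L, genome_length)
    } else {
      for (i in seq_len(nrow(sel))) {
        span <- (sel$start[i] + 1L):(sel$start[i] + sel$read_length[i])
        if (sel$strand[i] == "+") pos_counts[span] <- pos_counts[span] + 1
        else neg_counts[span] <- neg_counts[span] + 1
      }
    }
  }
  out <- data.frame(position = 0:(genome_length - 1L),
                    positive = as.numeric(pos_counts),
                    negative = as.numeric(neg_counts))
  attr(out, "length_class") <- length_class
  attr(out, "mode") <- mode
  attr(out, "n_reads") <- nrow(sel)
  class(out) <- c("coverage_profile", "data.frame")
  out
}

#' vpiRNA:vsiRNA proportion statistic
#'
#' The number of virus-derived 26-30 nt reads per 100 virus-derived 21 nt
#' reads. Undefined (flagged, not zero) when no 21 nt reads were observed.
#'
#' @param n_26_30 Count of virus-derived reads in the piRNA-size window.
#' @param n_21 Count of virus-derived 21 nt reads (vsiRNAs).
#' @param virus,tissue Optional labels carried into the result.
#' @return List of class `ratio_statistic`: `n_26_30`, `n_21`, `value`
#'   (reads per 100; `NA` when undefined), `undefined` flag.
#' @export
vpirna_vsirna_ratio <- function(n_26_30, n_21, virus = NA_character_,
                                tissue = NA_character_) {
  if (n_26_30 < 0 || n_21 < 0) stop("counts must be non-negative")
  undefined <- n_21 == 0
  structure(list(virus = virus, tissue = tissue,
                 n_26_30 = n_26_30, n_21 = n_21,
                 value = if (undefined) NA_real_ else 100 * n_26_30 / n_21,
                 undefined = undefined),
            class = "ratio_statistic")
}

#' @export
print.ratio_statistic <- function(x, ...) {
  if (x$undefined) {
    cat("vpiRNA:vsiRNA ratio undefined (no 21 nt reads)\n")
  } else {
    cat(sprintf("vpiRNA:vsiRNA ratio: %.1f per 100 (n26-30 = %d, n21 = %d)\n",
                x$value, x$n_26_30, x$n_21))
  }
  invisible(x)
}

#' Flag coverage hotspots
#'
#' Maximal runs of positions whose count reaches
#' `max(min_count, fold * median(nonzero counts))` on a strand, merged when
#' separated by at most `gap` positions below threshold. The fold/min-count
#' defaults are heuristic conventions of this package, not literature
#' values, and are echoed in the output.
#'
#' @param profile A [coverage_profile()].
#' @param fold Fold over the nonzero-median required (default 5).
#' @param min_count Absolute count floor (default 10).
#' @param gap Merge tolerance in positions (default 5).
#' @return `data.frame`: `start`, `end` (0-based half-open), `strand`,
#'   `fold_over_median`; zero rows when nothing exceeds the threshold.
#' @export
hotspot_flags <- function(profile, fold = 5, min_count = 10, gap = 5L) {
  stopifnot(inherits(profile, "coverage_profile"))
  out <- list()
  for (strand in c("+", "-")) {
    counts <- if (strand == "+") profile$positive else profile$negative
    nz <- counts[counts > 0]
    if (length(nz) == 0L) next
    med <- stats::median(nz)
    thr <- max(min_count, fold * med)
    above <- counts >= thr
    if (!any(above)) next
    # merge runs separated by <= gap positions
    idx <- which(above)
    breaks <- which(diff(idx) > gap + 1L)
    run_start <- idx[c(1L, breaks + 1L)]
    run_end <- idx[c(breaks, length(idx))]
    out[[strand]] <- data.frame(
      start = run_start - 1L,
      end = run_end,              # half-open
      strand = strand,
      fold_over_median = vapply(seq_along(run_start), function(j) {
        max(counts[run_start[j]:run_end[j]]) / med
      }, numeric(1)))
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), fold_over_median = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot a coverage profile
#'
#' Positive-strand counts above the axis, negative-strand below, in the
#' conventional two-color layout of strand-split small RNA maps.
#'
#' @param x A [coverage_profile()].
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coverage_profile <- function(x, main = "5'-end coverage", ...) {
  ylim <- range(c(x$positive, -x$negative, 1, -1))
  graphics::plot(x$position, x$positive, type = "h", col = "goldenrod2",
                 ylim = ylim, xlab = "reference position (nt)",
                 ylab = "5'-end read count (+ up / - down)", main = main, ...)
  graphics::lines(x$position, -x$negative, type = "h", col = "steelblue3")
  graphics::abline(h = 0, col = "grey40")
  invisible(x)
}

#' Write a coverage profile as TSV
#'
#' @param profile A [coverage_profile()].
#' @param path Output TSV path.
#' @export
write_coverage_tsv <- function(profile, path) {
  write_tsv(as.data.frame(profile), path)
}
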