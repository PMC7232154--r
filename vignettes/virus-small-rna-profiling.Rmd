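---
title: "Profiling virus-derived small RNAs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling virus-derived small RNAs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virnaprof)
```

## The biological question

Insects mount two distinct small RNA responses against replicating RNA
viruses. The siRNA pathway chops viral double-stranded RNA into 21 nt
virus-derived siRNAs (vsiRNAs) via Dicer-2; these map to both genome strands
and often pile up at hotspots near structured untranslated regions. The
piRNA pathway can additionally convert viral transcripts into 25–30 nt
virus-derived piRNAs (vpiRNAs). Canonical vpiRNA production leaves two
diagnostic marks: primary piRNAs begin with uridine (the **1U bias**), and
the secondary piRNAs produced by ping-pong amplification carry an adenine at
position 10 (the **10A bias**), because the two species overlap by exactly
10 nt at their 5′ ends and position 10 of the secondary is base-paired with
position 1 of the primary. Whether a given virus elicits vpiRNAs is
virus-specific: in multi-virus co-infections of *Aedes* mosquitoes, a
rhabdovirus can show a full ping-pong signature while co-infecting
flavivirus- and tetravirus-like agents produce only vsiRNAs plus unbiased
26–30 nt degradation fragments.

`virnaprof` implements the complete informatic chain needed to make those
calls from raw small RNA FASTQ files, and a simulator that generates
libraries with known ground truth so every statistic can be validated by
parameter recovery.

## Read cleaning

`trim_fastq()` applies three stages in a fixed order: 3′ adapter removal,
3′ quality trimming, then length filtering. Adapters are removed first
because in real libraries the adapter bases carry their own (often
synthetic) qualities.

* **Adapter trimming** finds the leftmost read suffix matching a prefix of
  the adapter with mismatch fraction ≤ `max_error_rate` (default 0.1) and
  overlap ≥ `min_overlap` (default 3). These defaults mirror common
  adapter-trimmer behavior. A consequence worth understanding: with an
  overlap floor of 3, about 4⁻³ of inserts end, by chance, in the
  adapter's first trinucleotide. On the full-length record those positions
  are rejected (the comparison window still contains the real adapter and
  mismatches accumulate), so error-free inserts are recovered at their
  exact length; but re-running the trimmer on its own output can remove
  such chance suffixes, because the comparison window has shrunk. We chose
  the recovery-preserving rule: a single pass is exact on error-free data,
  and strict idempotence additionally holds whenever `min_overlap` is large
  enough (≥ 8) that chance matches are negligible. The alternative — trimming
  chance 3′ k-mers eagerly so that a second pass is a no-op — silently
  shortens ~1.6% of clean reads and was rejected.
* **Quality trimming** uses the running-sum rule: among all cut points, it
  removes the suffix maximizing Σ(threshold − qᵢ), and leaves the read
  unchanged when no suffix has a positive sum. The default threshold is
  Phred 20. Ties favor the longer trim.
* **Length filtering** keeps reads of 19–33 nt, the gel excision window of
  standard small RNA preps; reads that became too short because quality
  trimming removed bases are attributed to `low_quality`, other out-of-window
  reads to `too_short`/`too_long`. The QC report always satisfies
  `reads_in = reads_kept + Σ discards`.

## Alignment

Reads are placed on each viral genome independently with at most **one
mismatch**, on both strands, following standard practice for virus-derived
small RNAs (short reads, no indels). The index stores the exact positions of
every 9-mer of the reference. Since the two terminal 9-mers of a ≥18 nt read
cannot both contain the same single mismatch, looking up both end seeds
enumerates every candidate placement (the pigeonhole principle); candidates
are verified by full Hamming comparison. `N` counts as a mismatch on either
side, and genome 9-mers containing `N` are not indexed because they can
never be the exact half of an admissible placement.

Reporting follows best-stratum single-placement semantics: a 0-mismatch
placement beats a 1-mismatch one, and ties within the best stratum are
broken uniformly at random under the run seed, so outputs are bit-reproducible.
A read may count once on each of several co-infecting viruses — mapping is
per-genome, not against a concatenated index. Internal coordinates are
0-based half-open; SAM output is 1-based with FLAG 16 and reference-forward
SEQ for minus-strand placements and the mismatch count in `NM`.

The RPM denominator is the number of reads kept after trimming. "Library
total" could also mean the raw read count; post-trim is used because it is
the quantity the pipeline controls exactly, and the choice is configurable
by passing a different total to `rpm_normalize()`.

## Profiles and the vpiRNA:vsiRNA statistic

`coverage_profile()` counts read **5′ ends**: the leftmost reference
position for plus-strand placements and the rightmost for minus-strand ones
(the biological 5′ terminus). One count per read makes conservation exact —
each profile sums to the number of reads in its length class. A per-base
mode is available for plotting full coverage.

The proportion of putative vpiRNAs to vsiRNAs is reported as the number of
virus-derived 26–30 nt reads per 100 virus-derived 21 nt reads. It is
undefined (flagged, not zero) when no 21 nt reads are observed, and is
invariant to library depth since both counts come from the same library.
The piRNA window defaults to 26–30 nt and can be widened (e.g. 26–32 nt)
via the `pirna_window` configuration key.

`hotspot_flags()` marks maximal runs of positions whose 5′-end count
reaches `max(min_count, fold × median(nonzero counts))`, merging runs
separated by at most `gap` positions. The defaults (fold 5, floor 10,
gap 5) are heuristic conventions of this package — hotspot calling has no
standard definition in the literature — and are echoed in the output so
downstream consumers can see what was applied. At shallow coverage
(< ~10 reads per hotspot position) the absolute floor dominates and no
hotspot is called; raise the depth or lower `min_count` for sparse data.

## piRNA signatures

`nucleotide_frequency_matrix()` anchors reads at their 5′ ends and reports
per-position A/C/G/U frequencies with coverage (the number of reads long
enough to reach the position, non-increasing along the read). Minus-strand
reads are analyzed in read space — the reverse complement of the
reference-forward stored sequence — so "position 1" is always the
biological 5′ nucleotide.

`bias_test()` is this package's operationalization of reading 1U/10A off a
heat map: an exact two-sided binomial test of the observed nucleotide count
against a background frequency, flagged only when significant at α = 0.01
*and* enriched above background. The background is the base composition of
the relevant strand of the viral genome, not 0.25: viral genomes are
compositionally skewed, and using the genomic composition keeps the false
positive rate at nominal level on degradation reads, which are genome
windows. The 1U test is applied to plus-strand reads and the 10A test to
minus-strand reads (the canonical assignment when primaries derive from the
positive-sense transcripts), but both assignments are computed and reported
by `run_pipeline()`.

`pingpong_overlap()` bins, for all opposite-strand read pairs in the piRNA
window, the 5′-to-5′ overlap (`q − p + 1` for a plus 5′ end at `p` and a
minus 5′ end at `q`) over 1–20 nt. The default weighting counts each
distinct (p, q) position pair at `min(multiplicity)` of its two ends, which
damps artifacts from a single amplified read pair; the `raw` mode counts
all read pairs and is what the quadratic all-pairs oracle in the test suite
reproduces exactly. `z10` standardizes bin 10 against the empirical mean
and SD of bins 1–9 and 11–20; no parametric null is claimed, and `z10` is
reported as `NA` unless at least two of those bins are nonzero. A planted
ping-pong fraction of 0.5 yields z10 ≫ 3; libraries of unbiased
degradation fragments give |z10| ≈ 1 with an argmax bin that is essentially
uniform over 1–20.

## The simulator and its ground truth

`simulate_library()` emulates the read classes observed in multi-virus
co-infection studies: 21 nt vsiRNAs from both strands with optional
hotspots, 26–30 nt primary/secondary vpiRNAs, strand-biased 26–30 nt
degradation fragments with no positional biases, and host background (a
21–22 nt plus 27–30 nt length mixture) drawn from an independent decoy
sequence (10 kb, uniform composition) so it maps to viral genomes only by
chance. Genomes are i.i.d. draws from a specified base composition; real
viral genomes have local structure the simulator does not model.

Two design points matter for interpretation:

* **Biases arise by conditional sampling, not base editing.** A primary
  piRNA with `p_1U = 0.9` is produced by drawing its 5′ position from
  genomic sites whose base is T with probability 0.9 (and from non-T sites
  otherwise); a ping-pong partner is placed on the opposite strand with its
  5′ end exactly 9 nt downstream of its template's, so its 10A is forced by
  complementarity, exactly as in the biology. Consequently every simulated
  insert is an exact genomic window (or reverse complement of one) whenever
  the sequencing error rate is zero — the invariant that underpins the
  round-trip and alignment-recovery tests.
* **The truth table is realized, not nominal.** Per (genome, class) it
  records the emitted count and the realized 1U/10A frequencies and strand
  split of the error-free inserts, so recovery tests compare measurements
  against what was actually drawn rather than against asymptotic targets.

Sequencing errors are uniform substitutions applied to the insert only (the
appended adapter is emitted faithfully); there are no indels, no
quality-score error profiles, no PCR duplicates, no ligation bias and no
UMIs. The relative abundance of host versus viral reads is not constrained
by any published value and is simply a recipe parameter. Passing tests on
simulated data therefore demonstrate correctness of the statistics and
their calibration under the stated generative model, not robustness to
artifacts real libraries may contain.

## Numerical and testing choices

* All randomness flows through explicit integer seeds (genome generation,
  class sampling, emission shuffling, alignment tie-breaks); fixed seeds
  give byte-identical FASTQ, SAM and TSV outputs.
* Degenerate inputs are defined, not fatal: empty FASTQ files yield
  all-zero reports; an all-zero profile yields no hotspots; a ratio with
  no 21 nt reads is flagged undefined; `library_total = 0` is an error
  because RPM is undefined.
* Parameter-recovery tests use 3 binomial standard errors for single
  quantities (1U, 10A, the ratio). Whole-matrix checks compare against the
  realized genome composition — the correct null, since even an i.i.d.
  "uniform" genome deviates from 0.25 — with a Bonferroni-adjusted z
  threshold at family α = 0.01. Negative controls run 20 seeds and demand
  bias flags off in ≥ 95% of them.
* Test problem sizes (genomes of 1.5–8 kb, libraries of 10²–10⁴ reads, a
  5 kb / 500-read brute-force alignment comparison) were chosen so the
  whole suite completes in about a minute while keeping every binomial
  band tight enough to be informative.

## Limitations

The aligner is exact but deliberately minimal: no indels, no quality-aware
scoring, no host-genome mapping and no BAM output. The hotspot caller is a
threshold heuristic, not a peak model. The bias test treats reads as
independent draws, which overstates confidence if one amplified duplicate
dominates a position (the weighted ping-pong mode mitigates the analogous
problem for overlap counting). Cross-library comparisons assume libraries
were prepared comparably; shares are computed on RPM by default precisely
because depths differ, but no batch-effect correction is attempted.
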