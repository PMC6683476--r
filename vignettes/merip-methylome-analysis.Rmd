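---
title: "Methods: transcript-space m6A methylome analysis with meripr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-space m6A methylome analysis with meripr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripr)
```

meripr analyzes MeRIP-seq (m⁶A-seq) experiments entirely in transcript
space: per-nucleotide IP and input fragment counts on mRNAs, peaks as
transcript intervals, topology relative to the coding region. This
vignette is the package's account of the statistical model, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design choices made where several readings were
defensible.

## Coordinates and transcript anatomy

All internal coordinates are 0-based, half-open; GFF3/GTF input
(1-based, closed) is converted once at the parsing boundary. Position 0
is always the transcript's 5′ end, on either strand, so downstream
arithmetic never branches on strand. The CDS interval
(`cds_start_t`, `cds_end_t`) *includes* the stop codon, and the anchor
for stop-centred windows is the **first base of the stop triplet**
(`cds_end_t - 3`); annotation conventions differ on whether "the stop
codon" means the triplet's first or last base, and fixing the first
base makes every downstream window deterministic.

The five-segment partition is:

| segment | definition (transcript space) |
|---|---|
| stop_codon | `[c − 50, c + 50)` for `c = cds_end_t − 3`, truncated at transcript ends |
| tss | `[0, min(100, cds_start_t))` |
| utr5 | remainder of `[0, cds_start_t)` |
| cds | `[cds_start_t, cds_end_t)` minus the stop window |
| utr3 | `[cds_end_t, length)` minus the stop window |

The stop window takes precedence over every other segment (it must:
the segments are defined as non-overlapping, and the window straddles
the CDS/3′UTR boundary by construction). The width of the TSS segment
is not a settled convention; we use the first `min(100, 5′UTR)` nt,
mirroring the stop window's 100-nt width. Both windows are arguments
(`stop_window`, `tss_window`) should a different convention be needed.
Summit-level assignment is used throughout (a peak belongs to the
segment containing its summit); assignment by whole-peak overlap is a
defensible alternative reading, but summit assignment is what makes
"each peak is assigned to exactly one segment" true without a
tie-break hierarchy.

Non-coding transcripts are retained for peak calling but excluded from
all segment mathematics, which is defined for mRNAs only.

## Peak detection and replicate consensus

Windows of 50 nt at 25-nt stride (half the ~100-nt fragment footprint,
so a site is always well covered by at least one window) are tested
with a one-sided Fisher exact test of the window's IP and input counts
against the library totals, and BH-adjusted **jointly across every
window of every transcript** — "FDR < 0.05" is read as a
transcriptome-wide statement, not per transcript. Significant windows
at most one stride apart are merged; the peak's p-value is its best
window's, and the summit is the position of maximum pseudocounted
normalized per-nucleotide enrichment, ties broken 5′-most so results
are deterministic.

A count-table exact test was chosen over a local-background scan
because in transcript space there is no "local background" distinct
from the transcript itself: the matched input library *is* the
background, fragment by fragment. The 0.5 pseudocount appears wherever
a ratio is formed and nowhere in the tests.

Consensus peaks implement the all-replicates rule: a region counts
only if every biological replicate called an overlapping peak, and the
reported interval is the intersection of the supporting peaks
(computed by depth-thresholded interval sweep, which equals the union
of all per-replicate-tuple intersections; the test suite checks this
equality against a brute-force all-triples oracle). The summit comes
from the supporting peak with the smallest p-value.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline's guarantees are stated.

* **Transcriptome**: by default 500 transcripts with uniform 5′UTR
  (50–300 nt), CDS (300–1500 nt, multiples of 3), 3′UTR (100–500 nt);
  a mix of strands and single/two-exon structures so coordinate
  conversion is always exercised. Base composition is mildly AT-rich
  (28/22/22/28), as plant mRNA is.
* **Sites**: 10% of transcripts carry one site, placed per segment
  weights concentrated on the stop window (0.50) and 3′UTR (0.30) —
  the canonical plant topology. 60% of sites carry a UGUAYY instance
  (Y drawn from C/U) centred on the site.
* **Counts**: input coverage averages 30× per nucleotide, scaled by a
  lognormal (sdlog 0.5) relative abundance. Each replicate draws one
  Gamma rate multiplier per transcript (variance = `dispersion`,
  default 0.05) **shared between that replicate's IP and input
  libraries** — both derive from the same mRNA preparation — and counts
  are Poisson given the rate. Marginally the counts are
  negative-binomial; conditionally the IP-vs-input contrast is
  calibrated, which is exactly the structure the Fisher test assumes.
  Setting `dispersion = 0` gives pure Poisson replicates.
* **IP signal**: inside a 100-nt fragment window around a site the IP
  mean is boosted by `1 + (E − 1)·s` (enrichment factor `E = 8`,
  stoichiometry `s = 0.8`), then all IP means are rescaled so the IP
  library depth matches its target — as real IP libraries are
  sequenced to a depth, not to a signal level.
* **Two conditions**: half the methylated transcripts are
  differential, 80% of them hypermethylated in condition B, with the
  fold change planted on the *measurable* enrichment scale
  (`(1 + (E−1)s_B)/(1 + (E−1)s_A)` = 3 by default). Differential
  transcripts also receive a 3× abundance change with sign opposite to
  the methylation change (`coupling = -1`), emulating the negative
  m⁶A–expression association seen in plant ripening tissue. The
  planted expression shift is set where a 3-replicate Welch test has
  high power, since the quadrant analysis is only informative about
  transcripts detected on both axes.
* **Determinism**: one master seed; condition/replicate streams are
  derived by fixed arithmetic offsets (`substream_seed`), so any
  subset of libraries is reproducible in isolation.

What the generator does **not** emulate: fragment-level positional
autocorrelation (counts are per-nucleotide draws, not overlapping
fragments), isoform mixtures, alignment artefacts, GC or length bias,
antibody off-target binding, and multiple sites per transcript.
Passing tests therefore demonstrate the *statistical logic* of the
pipeline under its stated assumptions — calibration, recovery, and
correct integration — not performance on any real library.

## Problem sizes used in the validation batteries

The test suite states its guarantees at desk scale, chosen as the
smallest sizes at which the corresponding effect is identifiable
rather than borderline:

* calibration and recovery: 500 transcripts, 3 replicates;
* differential m⁶A and the quadrant sign test: 300 transcripts
  (≈30–45 peaks, ~8–20 transcripts detected on both axes per run);
* motif recovery: 800 transcripts. This one deserves a note: with 60%
  motif planting the signal splits across the four Y-resolved UGUAYY
  hexamers, so each individual hexamer must clear a noise floor of
  4⁶ − 4 competing hexamers. At ~40 peaks a single hexamer's
  excess (~5 sequences) is comparable to the best-of-4096 null
  fluctuation; at ~80 peaks (~12 planted instances per hexamer) the
  top rank is reliably a UGUAYY match. This is a property of
  sequence-level hypergeometric scoring itself, worth remembering when
  interpreting motif ranks on small peak sets.

## Differential analysis choices

* Expression comes from the input libraries (FPKM), as the input
  fraction of a MeRIP experiment is an ordinary RNA-seq library.
* Differential expression is a two-sided Welch t-test on
  log2(FPKM + 1). This is a deliberate, clearly-labelled stand-in for
  assembly-based differential pipelines: with three replicates and
  planted fold changes it is the minimal replicate-aware test.
  Significance uses the raw p-value (< 0.05) with fold change ≥ 1.5
  (inclusive); BH-adjusted q-values are reported alongside.
* Differential m⁶A sums counts over replicates within condition
  (count-table differential tests are defined on pooled tables) and
  applies a two-sided Fisher test to `[[IP_A, in_A], [IP_B, in_B]]`.
  The regions tested are the union of the two conditions' consensus
  peaks, so a site methylated in only one condition is still testable.
* In the quadrant table a transcript with several peaks is represented
  by its most significant peak (smallest p; ties by largest |log FC|),
  and "unchanged" expression means failing either expression
  criterion.

## Assay calculators

CT technical replicates are averaged *before* exponentiation (the
standard ΔΔCT practice; exponentiating first would bias the estimate
upward under CT noise). Standard curves are ordinary least squares
with a free intercept — forcing through the origin is common but not
universal, and a free intercept subsumes the forced case when the
blank truly reads zero. Bisulfite clones must arrive pre-aligned and
gap-free; alignment is out of scope precisely so the per-site C/T
arithmetic stays exactly testable. No bisulfite conversion-efficiency
correction is applied; levels are raw C/(C+T) ratios. Cytosines with
no C or T call (all clones mismatched) are excluded with a warning
rather than imputed.

## Numerical conventions

* Pseudocount 0.5 in every enrichment ratio; pseudocount 1 inside
  log-transforms for correlation and t-tests.
* BH is `stats::p.adjust`; Fisher tails are `stats::phyper` /
  `stats::fisher.test`.
* All ties (summits, motif ranks, representative peaks) break
  deterministically (5′-most / alphabetical / largest effect).
* Degenerate inputs error early and by name: non-coding transcripts in
  segment math, empty CT groups, curves with < 3 points or
  non-increasing concentrations, zero expressed transcripts in the
  peaks-per-expressed ratio.

## Known limitations

Peak boundaries are window-quantized (multiples of the stride), so
reported intervals are wider than the underlying 100-nt signal; the
summit, not the boundary, is the position estimate. The Fisher window
test treats nucleotides as independent fragments, which is
anti-conservative for strongly autocorrelated real coverage — on real
libraries the replicate-consensus requirement is the main false-positive
control, as it is here. Sequence-level motif counting ignores
occurrence multiplicity, and the differential expression stand-in does
not model count uncertainty at low FPKM.
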