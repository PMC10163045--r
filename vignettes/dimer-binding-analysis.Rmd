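---
title: "Distinguishing heterodimer from homodimer DNA binding: methods"
author: "dimerspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing heterodimer from homodimer DNA binding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerspec)
```

# The problem

DAP-seq assays the genome-wide binding of an in-vitro expressed
transcription factor on naked genomic DNA; double DAP-seq (dDAP-seq)
co-expresses two differently tagged factors and purifies through one
tag, so that the recovered fragments report heterodimer binding.  For
dimerizing families such as the plant bZIPs — where group C members bind
DNA only when partnered with group S1 members — the scientific question
is comparative: *where does the heterodimer bind that the homodimer does
not, and which DNA sequence elements explain the difference?*

dimerspec implements the computational path from peak calls and counts
to that answer: artifact filtering, binding-profile comparison,
differential-binding classification, k-mer motif-category enrichment,
and peak-to-gene target association.  A seeded simulator generates data
with known ground truth so every stage is verifiable.

# Models and procedures

## Blacklist and consensus peaks

Negative-control purifications (empty vectors, tag-only pulldowns)
produce recurrent artifact regions.  Regions covered by peaks of at
least `min_shared = 5` distinct control samples form the blacklist;
within one control, overlapping peaks are collapsed first so a single
sample cannot contribute depth 2.  Peaks touching a blacklist region by
a single base are removed whole — removal, not trimming, because a peak
whose signal overlaps an artifact cannot be trusted in part.  An open
choice here is whether replicate control samples should count separately
toward the depth; we cap the contribution at one per control set, the
conservative reading.

The consensus peak set used for cross-sample correlation keeps regions
present (≥ 1 bp overlap) in at least `min_overlap = 2` samples,
re-centers each contributing peak on its reported summit (midpoint when
absent) and expands it by `summit_pad = 100` bp each way — every
pre-merge consensus interval is therefore exactly 200 bp — and merges
overlapping intervals.  "Presence" is defined by any overlap because no
overlap fraction is part of the procedure's definition; the fixed width
makes per-region counts comparable across samples.

## Binding correlation

For the correlation analysis, the consensus is filtered to the regions
overlapping any replicate's `top_n = 3000` most enriched peaks (ranked
by −log10 q, ties by fold enrichment, then coordinate for determinism;
replicates with fewer peaks contribute all of them).  Per-sample
profiles are `log2(normalized count + 1)` averaged over replicates; the
pseudocount of 1 keeps zero counts finite and is configurable.  Samples
are clustered by average linkage on `1 − Pearson r` distances, the
standard choice for binding-profile heatmaps; the implementation is
`stats::hclust`, and the test suite checks its heights against an
explicit O(n³) re-derivation.

## Differential binding

The comparison of one heterodimer (dDAP-seq) against the corresponding
homodimer (DAP-seq) experiment is a compact re-statement of the
MAnorm2 approach, not a line-for-line port:

1. **Normalization** on `log2(count + 1)`.  Within each condition,
   every replicate is linearly mapped (median and MAD matched on
   commonly occupied peaks) onto the condition's first replicate; the
   two condition profiles are then rescaled symmetrically to their
   common location and scale.  Robust location/scale estimators resist
   a minority of truly differential peaks; the symmetric between-step
   makes label swapping an exact mirror (every log2 fold change negates,
   p-values unchanged), which the suite tests.  "Occupied" means a raw
   count of at least 10 in every sample — the occupancy definition is a
   tuning constant exposed as `occupancy_min`.
2. **Mean–variance curve.**  Per-peak pooled within-condition variances
   are regressed on per-peak means with `lowess` on the log variance.
   Because `E[log s²] = log σ² + digamma(d/2) − log(d/2)` for
   chi-square-distributed variances, the fit is corrected for that bias
   before exponentiation — without it the curve underestimates the
   variance by ~25% at 4 residual d.f.  A log-linear parametric fit is
   the fallback when the local fit degenerates; all-zero variances are
   an error, since they mean the replicates are copies.
3. **Prior degrees of freedom** come from the spread of
   `log(observed/fitted)` variance ratios: for chi-square variances this
   spread is `trigamma(d1/2) + trigamma(d0/2)`, so `d0` is obtained by
   inverting the trigamma function (bisection).  When the observed
   spread is no larger than the sampling spread, `d0 = Inf` and the
   curve is used directly.
4. **Moderated t-test.**  The per-peak variance is shrunk toward the
   curve with weight `d0/(d0+d1)`, the two-sided p-value uses `d0+d1`
   degrees of freedom, and BH adjustment runs over all peaks.  Peaks
   with adjusted p < 0.05 are `heterodimer_specific` when the fold
   change (heterodimer − homodimer, log2) is positive and
   `homodimer_specific` when negative.

Under a null simulation (no planted differences, negative-binomial
counts, 3 vs 3 replicates) the observed fraction of adjusted p < 0.05
is essentially zero — the moderated test is conservative at the null,
which is the safe side for a classifier feeding motif analysis.

## Motif categories and enrichment

The k-mer category system captures the elements that distinguish bZIP
dimer classes: the CRE-like element `TGACGTCA`, the TRE-like element
`TGACTCA`, the four ACGTG elements varying at the position before ACGT,
and the 4-mers `TGAC`, `TGAG`, `TGAT`.  Two rules matter:

* **Exclusion.**  A `TGAC` match counts as a half-site only when its
  footprint is not entirely inside a same-strand CRE-like match;
  likewise `TGAG` outside TRE-like matches.  Taken literally, a `TGAC`
  inside a TRE-like match *does* count (the exclusion names only the
  CRE-like parent); `kmer_categories("extended")` additionally masks
  those, because the narrower reading is also defensible.  The default
  is the literal rule.
* **Deduplication.**  Presence is binary per category per peak —
  multiple matches in one window count once.

Scanning covers the 150 bp window centered on the peak midpoint, on
both strands by default (DAP peaks are unstranded; a palindrome such as
`CACGTG` yields one presence, not two).  `N` never matches.  The scanner
is verified exactly against a naive position-by-position oracle on
10,000 random 150-mers.

Enrichment between heterodimer- and homodimer-specific peaks is a
one-tailed Fisher exact test per direction on the 2×2 class-by-presence
table, BH-adjusted across categories within each direction, reported as
a log2 odds ratio with Haldane correction (+0.5 per cell) when a cell is
zero.  Note a practical regime effect: a 4-mer half-site occurs in most
150 bp windows by chance (expected ≈ 1.2 occurrences on two strands),
so planted-rate contrasts are attenuated for 4-mers and are sharpest
for the 6–8 bp elements; this mirrors real data, where half-site
enrichment is measured within motif-match instances rather than raw
windows.

`ksm_lite_discover` is a deliberately small k-mer discovery tool: the
background is a per-sequence dinucleotide (Altschul–Erickson Eulerian)
shuffle, preserving each sequence's dinucleotide counts exactly, and
each strand-collapsed k-mer (lengths 5–14 by default) is scored by a
one-sided hypergeometric test of sequence-level presence.  It is a
stand-in for full k-mer set memory (KSM) models, which align k-mers
with flanking context and positional weighting — out of scope here.

## Target scores and the mHG test

Each gene's distance `d(g)` is from its TSS to the nearest peak summit
on the same chromosome (arithmetic distance; genes on peak-less
chromosomes score 0).  The score transform is
`score(g) = 1 − ECDF(d(g))` with mid-rank ties, using the empirical
distribution of distances over all genes — a monotone, scale-free
mapping that implements "score by the overall distribution of
peak-to-gene distances".  It is not claimed numerically identical to any
external package's transform.  Per-gene q-values come from `B = 200`
uniform re-placements of the summits per chromosome, with an add-one
permutation p-value and BH adjustment; below `B = 100` the function
warns that q-values are unstable.  The TSS-to-summit convention (rather
than peak edge) is the default because summits are the best point
estimate of the binding site.

The minimal hypergeometric test takes a ranked binary membership vector
and minimizes, over all prefixes `n`, the hypergeometric upper tail
`P(X ≥ k(n))` with `X ~ Hypergeom(N, K, n)`.  Because the minimum over
prefixes is itself a selection, the statistic is not a p-value; the
exact p-value is the probability, under the uniform distribution on the
`C(N, K)` arrangements, that the minimal tail is at most the observed
one.  It is computed by a forward pass over prefix states `(n, k)` in
probability space: each state carries the probability that a random
arrangement reaches it without having entered the rejection region, and
region mass is absorbed as reached.  Working in probability space (not
path counts) avoids combinatorial overflow at any N.  Ties in the tail
comparison use a 1e−12 relative tolerance.  The suite checks the DP
against full enumeration for every vector with N ≤ 12, K ≤ 6, and the
analytic bounds `statistic ≤ p ≤ N · statistic` on random vectors.
The XL extension (lower bounds on counted prefixes) is not implemented;
the plain test corresponds to X = 1, L = N.

Gene-set rankings break score ties lexicographically by gene id so that
results are reproducible across platforms.

## Window peak caller

A desk-scale stand-in for point-source peak callers, used for control
samples and simulations: the genome is tiled (non-overlapping windows),
window counts of 200 bp-extended fragments are tested against a
control-scaled local Poisson rate (floored at the global rate), BH
correction runs across windows at q ≤ 0.01, adjacent significant
windows merge, and each peak reports its maximum-coverage summit, fold
enrichment and −log10 q.  It makes no claim to the event-resolution of
EM-based callers.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with defaults chosen once as a realistic small study:

* **Genome**: 2 chromosomes × 500 kb of i.i.d. bases at GC 0.36
  (Arabidopsis-like).  No repeats, isochores or methylation — the
  simplest null under which motif counts are analyzable.
* **Genes**: 600 non-overlapping bodies of 0.5–2 kb, random strands,
  placed by stick-breaking of the free space.
* **Peaks**: 300 shared + 150 heterodimer-specific + 150
  homodimer-specific, 400 bp, non-overlapping; 30% anchor within
  ±300 bp of a gene TSS, and those genes are the true targets.
* **Motif planting**: class-dependent category rates applied in the
  150 bp midpoint window (defaults: heterodimer peaks TRE-like 0.6 and
  TGAC half 0.6; homodimer peaks G-box 0.6 and GC-hybrid 0.3; shared
  peaks G-box 0.3 and TGAC half 0.3 — the "type II" contrast).  Planted
  k-mers never overlap one another, and a half-site is re-drawn if its
  flanks would accidentally complete its parent element, so the ledger
  is unambiguous.
* **Counts**: negative binomial with dispersion 0.1 (real dDAP-seq
  replicate dispersion is not published; 0.1 is a typical value for
  well-behaved ChIP-like replicates and is exposed in the
  configuration, not asserted).  Condition-specific peaks have
  bound/unbound mean ratio `fold_change = 4`; replicate depth factors
  are log-uniform in [0.7, 1.4], enough to exercise normalization
  without dominating the signal.  Fragment-level simulation is skipped:
  the analysis consumes MAPQ-filtered counts, so counts are emitted
  directly.
* **Controls**: 6 samples; each of 5 artifact regions (1 kb) appears at
  identical coordinates in at least `max(5, n_controls − 1)` controls,
  so the blacklist rule recovers them exactly; 20 private noise peaks
  per control.
* **DEG set**: 80% of true targets plus an equal number of random
  non-targets (the random fill is configurable, including zero).

What the generator does *not* emulate — sequence composition biases,
chromatin accessibility, fragment-length variation, summit offset
error, GC-dependent amplification — bounds what passing tests show:
they validate the algorithms' correctness and calibration on data
satisfying their assumptions, not robustness to every artifact of real
libraries.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open on disk (BED/narrowPeak) and
  1-based closed in memory (GRanges); conversion happens only at I/O.
* All ranking ties break deterministically (coordinate, adjusted p,
  gene id) so equal inputs give byte-equal outputs.
* `log2` pseudocount 1 throughout; configurable where it matters.
* Degenerate inputs error loudly: empty peak-set lists, all-zero
  variances, all-0/all-1 membership vectors, zero library sizes,
  category tables with non-ACGT k-mers.
* Every stochastic function takes or derives a seed; the pipeline
  derives one sub-seed per stage from the run seed, so stage outputs do
  not depend on execution order.

# Problem sizes

The shipped tests and the acceptance script run the full pipeline on
the demo configuration (2 × 300 kb, 310 peaks, 2 + 2 replicates), the
exhaustive mHG check at N ≤ 12, K ≤ 6, the Fisher oracle over all 2×2
tables with N ≤ 30, the scanner oracle on 10,000 150-mers, a 100-seed
null FDR simulation at 10,000 peaks, and a 50-seed motif-direction
recovery at 500 peaks per class.  These sizes were chosen as the
smallest at which the Monte-Carlo assertions are stable.

# Known limitations

* The differential module is a two-condition comparison; multi-dimer
  joint models are out of scope.
* The mHG implementation is exact but O(N·K) per evaluation; for gene
  universes in the tens of thousands with large K it is the slowest
  step of `rank_and_test`.
* The closest-gene transform and permutation q-values follow the stated
  principle of the distance-distribution score but are not a
  re-implementation of any specific package.
* Gene-set enrichment treats annotations as flat gene→term maps; no
  ontology topology or term propagation.
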