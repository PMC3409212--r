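---
title: "Methods: copy-number aberration analysis of tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number aberration analysis of tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidycna)
```

`tidycna` implements the full analysis chain for somatic copy-number
aberration (CNA) cohorts profiled on dense probe arrays, in the style used
for large stage-II/III colorectal cancer series: probe-level profiles are
quality-controlled, centered and segmented; segments are classified into
five dosage bins; and the classified cohort feeds recurrence, focal-peak,
group-comparison, dosage–expression, network and survival analyses. This
vignette is the package's account of each model, the parameters that
matter, and the design decisions taken where the conventions of the field
leave room.

## Coordinates, scales and conventions

All internal coordinates are 0-based half-open; files (SEG, probe matrices)
are 1-based (SEG inclusive), converted exactly once at the I/O boundary.
Copy number is carried as absolute copies with diploid = 2.0, because every
classification threshold is stated in copies; log2-ratio SEG input is
converted via `CN = 2·2^log2ratio` on read. Sex chromosomes are parsed and
tagged but excluded by contract from event counts, clustering and the
analyses downstream of them.

## Sample QC and centering

MAPD is the median of `|v[i+1] − v[i]|` over consecutive probes, never
across a chromosome boundary; it estimates per-probe noise robustly to real
copy-number steps (a genome of segments contributes only its few
breakpoints to the median). Samples above the conventional 0.6 cutoff are
removed. For i.i.d. Gaussian probe noise of standard deviation σ, MAPD ≈
1.35 σ/√2 ≈ 0.95 σ, so the cutoff corresponds to σ ≈ 0.63 copies.

Centering anchors the mode of each sample's probe-value density at 2.0
(kernel density, default bandwidth): tumor genomes are mostly diploid, so
the dominant mode is the diploid cluster even with 40% of the genome
aberrant. When a normal-tissue baseline cohort is supplied, each probe is
first divided by the baseline median at that probe (removing probe response)
and rescaled to copies before mode anchoring.

## Segmentation

Circular binary segmentation is applied per chromosome: the best arc
`(i, j]` maximizes `T = |mean_in − mean_out| / (s·sqrt(1/k + 1/(n−k)))`,
with `s` the standard deviation of the current segment. The scan is exact
and O(n²) (for each arc length the statistic is linear in the windowed sum,
so only the extreme windows need evaluation) and runs in compiled code; the
recursion splits accepted arcs and continues on the parts.

**Split significance is a hybrid rule.** A pure permutation p-value cannot
resolve the conventional cutoff `alpha = 1e-6` with any affordable number
of permutations (the smallest attainable p with 10,000 permutations is
about 1e-4). A split is therefore accepted immediately when the
conservative all-arcs bound `n(n−1)·Φ(−T_max) ≤ alpha` holds — if even this
upper bound on the p-value is below alpha, the true p is too — and only
otherwise falls back to label permutations with early stopping in both
directions. At `alpha = 1e-6` the bound decides essentially every case (it
requires `T ≳ 6.6` at n = 200), which also makes the default segmentation
deterministic; the permutation path matters for looser alphas. On 1,000
simulated pure-noise chromosomes of 200 probes the default settings produce
zero splits.

**Rank transform.** A rank version of the statistic is available
(`use_ranks = TRUE`) and is robust to gross outliers, but it is *not* the
default, because the rank statistic is bounded: for a k-probe arc its
maximum attainable value is `1.73/sqrt(1/k + 1/(n−k))` regardless of the
event's amplitude, which stays below the `alpha = 1e-6` acceptance
threshold for events shorter than ~16 probes. With ranks as default, short
high-amplitude amplicons would be structurally undetectable at the stringent
alpha; the classical value-based statistic has no such ceiling.

Post-processing: segments shorter than `min_probes` (default 3) are
absorbed into the neighbor with the closer mean; adjacent segments whose
means differ by less than `merge_tol` (default 0.3 copies, well below the
one-copy spacing of true states) are merged, closest pair first. Segment
means are always computed from the original values and floored at zero
(copy number is physically non-negative; noise around a homozygous deletion
can otherwise average fractionally below zero after centering). The
probe-count-weighted mean of segment means equals the chromosome probe mean
exactly.

## Classification and event counting

Five bins in copies: amplified (> 3.8), gained (2.3–3.8), unchanged
(1.7–2.3), deleted (0.5–1.7), homozygously deleted (< 0.5). The stated
ranges touch at 1.7, 2.3, 3.8 and 0.5; ties are resolved toward the
no-call-ward bin (1.7 and 2.3 are unchanged, 3.8 gained, 0.5 deleted) —
a conservative, test-pinned policy.

A per-tumor "CNA event" is a maximal run of adjacent same-direction
non-neutral segments on one chromosome: a gained segment abutting an
amplified one is one gain event; the same for deletions. This matches the
magnitude of reported per-tumor CNA counts in the field better than raw segment counts,
which are inflated by within-event splits. Sex chromosomes are excluded
(configurable).

Frequency tracks report, at each marker (the probe grid by default, or a
fixed 100-kb grid for cross-cohort work), the fraction of samples whose
covering segment is gained-or-amplified and deleted-or-homodeleted; a
sample with no covering segment counts as unchanged there.

## Recurrence: MCRs and the STAC-style test

Candidate recurrent regions are maximal marker runs with frequency ≥ 10%;
within a run the minimal common region (MCR) is the contiguous plateau
attaining the run's maximum — the smallest interval shared by the largest
set of overlapping events — reported with its carrier set. Significance
uses a STAC-style permutation test with the *frequency* statistic: under
the null, each sample's aberration intervals are re-placed uniformly
(lengths preserved, no wrapping) along the chromosome, and a region's p is
the fraction of permutations whose maximum marker count anywhere on the
chromosome reaches the observed plateau count (max-statistic correction).
The footprint statistic of the original STAC formulation is not
implemented: frequency is the quantity the downstream filters and reports
use. Regions are flagged at p < 0.01.

A structural caveat worth knowing: the re-placement null has no power
against whole-chromosome events (an interval as long as the chromosome
lands on itself), and little against near-arm-length events. Arm-level
recurrences are therefore established by the frequency track and group
tests, while the STAC p is informative for sub-chromosomal regions — the
regime it was designed for.

## Focal analysis (GISTIC-style)

Per sample and chromosome arm, the arm-median marker copy number is
subtracted; the positive remainder is focal amplification amplitude, the
negated negative remainder focal deletion amplitude (in copies — the same
scale as the bins). The G-score at a marker is the cohort sum of
amplitudes. The null circularly shifts every sample's amplitude vector
within each chromosome by an independent uniform offset per permutation,
preserving each sample's amplitude spectrum and autocorrelation while
decoupling positions across samples; empirical p compares the observed
score against the pooled permuted scores, and q is Benjamini–Hochberg over
markers (cutoff 0.25). Peaks are called iteratively: take the maximum-G
significant marker, extend to the surrounding significant run, trim by
leave-one-out (drop the largest contributor at the peak and re-extend),
record, subtract the carriers' amplitude over the run, and recompute
against the original null until nothing passes. Each iteration strictly
reduces amplitude mass, so peel-off terminates.

This is a deliberately reduced reading of GISTIC 2.0: no arbitrated
broad/focal decomposition, no gene-level GISTIC, no confidence ("wide
peak") intervals. What is preserved is the scientific semantics — recurrence
× amplitude with a focal emphasis and a genome-wide null.

## Group comparisons and clustering

Frequency comparisons between groups (MSI vs MSS, stage II vs III) use a
two-sided Fisher exact test per marker on the directed 2×2 carrier table,
flagged only when both rules hold: absolute difference > 15 percentage
points and p < 0.01. The two rules are independently toggleable; no
multiple-testing correction is applied to the flag (matching the stated
procedure), but a BH-adjusted column is always emitted alongside. The
percentage-point reading of the 15% rule is adopted (a 24.2% vs 7.1%
contrast, 17.1 points, is then correctly significant). Burden differences
use the Welch (unequal-variance) t-test, appropriate when group spreads
differ several-fold.

Clustering is agglomerative with complete linkage on Euclidean distances
over gene-level copy number (1 − Pearson available by option; the metric is
not fixed by convention), cut at k = 3 by default. Sex-chromosome genes in
the input are an error, so their exclusion is always explicit. Cluster ×
label enrichment is a two-sided Fisher test per (cluster, label level),
missing labels excluded pairwise.

## Gene-level copy number, cis concordance, pathways

A gene's copy number in a sample is the *unweighted* mean of the mean
copy numbers of all segments overlapping the gene interval (the stated
convention; a length-weighted variant exists behind a flag), missing where
nothing overlaps. Splitting a segment without changing its value leaves
every gene value unchanged.

Cis concordance categorizes samples by the gene's CNA class, centers
expression per gene, and tests the monotone trend of expression across the
ordered classes with the Jonckheere–Terpstra statistic (normal
approximation, two-sided), alongside Spearman rho on the numeric values.
The JT choice is an artifact decision — any monotone-trend test over
ordered dosage classes would serve — and genes lacking two classes with at
least two samples are flagged untestable rather than tested.

Pathway over-representation of (typically) amplified-peak genes uses the
one-sided hypergeometric p (the question is over-representation, and a set
disjoint from the hits must score p = 1; a two-sided test would flag
depletion). Sets are intersected with the user's gene universe and
filtered to 10–500 members. Fold enrichment is
`(k/|hits|)/(|set|/|universe|)`. The permutation FDR draws, per permutation,
one random same-size set per tested set and uses the plug-in estimator
`FDR(s) = mean_b #{random p ≤ p_s} / #{observed p ≤ p_s}`, capped at 1,
with 100 permutations by default; descriptions of this
estimator is loose, and this is the documented reading.

## Correlation networks

Gene–gene Pearson correlations across samples (pairwise complete, pairs
with < 3 complete observations undefined) separate *linked* (same
chromosome) from *unlinked* pairs; unlinked correlation is the signal of
co-selection. The edge graph connects pairs with |r| ≥ 0.3, optionally
restricted to unlinked pairs; the degree distribution is summarized by
binned counts and the OLS slope of log-count on log-degree — a scale-free
*style* summary, deliberately not a formal power-law fit. The randomization
null shuffles sample labels independently per chromosome, which preserves
every within-chromosome correlation exactly (assertable equality) while
destroying cross-chromosome structure; observed vs pooled-null degrees are
compared by a two-sample Kolmogorov–Smirnov test.

Note that per-tumor burden heterogeneity (overdispersed event counts) by
itself induces genome-wide positive cross-chromosome correlation — high-burden
tumors are aberrant everywhere. The null comparison is therefore expected to
reject on realistic cohorts even before co-selection of specific loci; the
specific co-selected pairs are read from the edge list, not from the global
test alone.

## Survival scans

Each region (MCR or focal peak) defines carriers as samples whose
copy-number class at the region midpoint matches the region's direction.
For every region × endpoint (OS, RFS) × stratum (stage II, III, combined),
a standard two-group log-rank test (1 df) is computed with Kaplan–Meier
curves; direction comes from the sign of observed-minus-expected events in
carriers. Flags use the unadjusted p < 0.01 — mirroring common practice —
but the scan is heavily multiple, so a BH-adjusted column per
endpoint-stratum scan is always emitted alongside; degenerate strata (no
carriers, no events) are skipped with warnings. No covariate adjustment or
Cox modeling is attempted.

## The synthetic cohort generator

The generator exists so that every stage is testable against known truth.
Its defaults are fixed study conditions, not tuning knobs:

* 269 MSS and 33 MSI samples; stage II/III split 30/239 within MSS.
* Per-tumor background event counts negative-binomial matched to
  33.2 ± 17.6 (MSS) and 10.2 ± 6.5 (MSI) — only the first two moments are
  specified, and the NB is the standard overdispersed count model.
* Planted events at fixed cohort frequencies: arm gains of 20q (72.5%),
  13q (51.0%), chromosome 7 (41.8%), 8q (33.1%); chromosome-18 loss
  (58.6%); focal deletions at a 16q23.1-like locus (24.2% of MSI vs 7.1% of
  MSS), a 20q11.1-like locus (24.4% vs 8.9%) and a 3p14.2-like locus
  (24.3% of stage III vs 3.3% of stage II); and two high-amplitude focal
  amplicons (12p13.33-like and 20q13.33-like, copy number 6, ~10%/8%).
  Carriers are independent Bernoulli draws within the eligible group;
  `simulate_correlated_events()` swaps in a Gaussian copula to plant
  co-selection with preserved marginals.
* The genome is a miniature: human chromosome proportions scaled 1/20 with
  25-kb probe spacing (~6,000 probes). The scale is chosen so that a
  full cohort simulates and segments in seconds while the *smallest*
  events still span ≥ 20 probes — on real molecular-inversion-probe arrays
  a megabase event covers hundreds of probes, and an event spanning only a
  handful of probes would be unrepresentatively hard to detect at
  `alpha = 1e-6`.
* Background events have lengths log-uniform between 0.5 Mb (20 probes) and
  the containing arm, direction ±1 copy equiprobably, and are placed by
  rejection sampling so they overlap neither each other nor any planted
  locus (guard gap 0.25 Mb). This makes the drawn count the realized count
  (burden moments are preserved exactly up to sampling) and keeps planted
  frequencies exact at planted loci; when placement fails after bounded
  retries in extreme-burden tumors the event is dropped and the truth
  records what was realized. Overlaps that do occur (planted × planted, as
  with a deletion inside a gained arm) add in copy number, floored at zero.
* Per-probe Gaussian noise, default σ = 0.25 copies (MAPD ≈ 0.24, a typical
  passing FFPE sample). Expression follows
  `expr = 1.0 + 0.5·CN + N(0, 0.5)` per gene on a regular ~250-gene model.
  Survival is exponential (baseline median 60 months OS, 48 RFS) with a
  hazard ratio of 0.5 on OS for 20q-gain carriers, censored uniformly over
  a 60–120-month follow-up window.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: FFPE-specific noise spectra and wave
artifacts (noise is white Gaussian), probe-specific response (probes are
exchangeable), subclonality (events are clonal integer shifts), allelic
structure, real gene density and linkage geometry, and any coupling between
burden and survival beyond the planted hazard ratios. Conclusions about
those require real cohorts; the generator establishes that the *pipeline*
recovers what its own model plants, at realistic magnitudes.

## Problem sizes and determinism

All stochastic stages take explicit seeds, stage-scoped so any stage can be
re-run in isolation; fixed seeds give byte-identical outputs end to end.
The test suite exercises full-size cohorts (302 samples) across 100 seeds
for burden recovery, 20 seeds for the group-restricted deletion contrasts,
1,000 null chromosomes for segmentation calibration, 500 null chromosomes
for STAC calibration, 200 null cohorts for focal-peak calibration and 500
null replicates for log-rank calibration; these sizes balance Monte-Carlo
resolution against a test run of a few minutes. Tiny-instance oracles
(exhaustive arc scan, exhaustive STAC placement enumeration, hypergeometric
enumeration, an independent log-rank score test) pin the implementations
exactly.

## Known limitations

* CBS significance at extreme alphas rests on a conservative normal-tail
  bound; true split p-values near the threshold are over-estimated, so
  borderline change-points are dropped rather than over-called.
* The STAC null is powerless for whole-chromosome events (above).
* The focal analysis is a reduced GISTIC (no wide-peak confidence
  intervals, no broad/focal arbitration), and peel-off re-uses the original
  permutation null rather than re-permuting after each peak.
* The per-marker Fisher scan and the survival scan report unadjusted p by
  design; the emitted BH columns should be consulted whenever the scans are
  used for discovery rather than for reproducing the conventional
  procedure.
* The generator's additive integer-event model has no subclonal fractions;
  dosage classes are therefore crisper than in real tumors, and cis
  concordance power on real data will be lower than on simulated cohorts.
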