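---
title: "condseg: models and methods"
author: "condseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{condseg: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

condseg identifies genomic regions with the hallmarks of
transcriptional condensates: clusters of enhancer-dense genome
segments that interact strongly in 3D space. Transcriptional
condensates are membraneless nuclear bodies thought to assemble by
liquid–liquid phase separation of transcription factors and
co-factors at highly active loci, frequently seeded by super-enhancer
regions. The package works from three kinds of evidence:

1. **1D activity tracks** (ChIP-seq of histone marks and transcription
   factors, ATAC-seq accessibility), binned on a fixed genomic grid;
2. **a genome segmentation** of the reduced 1D signal into
   homogeneous blocks;
3. **normalized chromatin-contact scores** (Hi-C derived), pooled per
   segment pair.

The pipeline has four stages — reduction, segmentation, annotation,
and contact integration — each exposed as ordinary functions so any
stage can be run, inspected or replaced on its own. The final calls
are *putative transcriptional condensates* (PTCs): connected
components of enhancer-enriched segments joined by above-threshold
median contact scores.

# Signal reduction

Tracks are binned at a fixed resolution (default 5 kb — coarse enough
that chromatin-contact data remain informative per bin, fine enough to
resolve enhancer-scale features). Binning distributes interval signal
mass length-proportionally, so total mass is conserved exactly. Tracks
can be depth-normalized per bin (`cpm`, `rpkm`) before analysis.

The bins × experiments matrix is reduced to one dimension by PCA and
only the first component (PC1) is kept as the segmentation signal. By
default PCA runs on standardized values — each track transformed as
`z = (log10(x + 1) − mean)/sd`, with the *population* SD convention —
which is effectively correlation-mode PCA. This choice is deliberate:
with activity tracks of very different dynamic ranges,
covariance-mode PCA on raw counts would be dominated by the deepest
library, whereas on standardized values every track contributes on an
equal footing and all activity tracks load positively and
near-equally on PC1. Users who prefer PCA on untransformed normalized
counts can pass `assay(btm)` to `computePC1()` directly; the
standardized route is the default. The PC1 sign is arbitrary from the
eigendecomposition, so it is oriented to correlate non-negatively
with the per-bin mean signal (high PC1 = high joint activity); in the
degenerate case of exactly balanced anti-correlated tracks the first
loading is made non-negative instead.

The log-transform pseudocount defaults to 1.0; any positive value
works, and with depth-normalized inputs the value mostly shifts the
zero bins relative to the signal bins.

# Segmentation

PC1 is treated as a serial signal over chromosome coordinates and
segmented with a piecewise-constant mean changepoint model. For a
fixed number of breaks *m*, break positions minimize the residual sum
of squares globally, by dynamic programming over prefix sums, subject
to a minimum segment length — the classical multiple-structural-break
construction for regression on an intercept. The structural-break
F-test (Chow test) view and this RSS view select identical break
positions; `breakFStatistics()` reports the per-break F statistics
for inspection. The number of breaks is then chosen by BIC,

```
BIC(m) = n log(RSS_m / n) + (2m + 2) log(n),
```

counting the m break dates, the m + 1 segment means and one variance;
ties resolve to the smaller m, so constant signals always return zero
breaks.

Because the exact DP is quadratic in the window length, chromosomes
are scanned with overlapping sliding windows — default 1000 bins
(5 Mb) slid by 500, with the final window right-anchored at the
chromosome end so tails are scanned with full context. The minimum
segment size defaults to 5% of the window (250 kb at 5-kb bins),
which also caps the breaks per window at `floor(1/0.05) − 1 = 19`.
Boundaries reported by different windows for the same true change
land within a few bins of each other, so window-level boundaries are
merged by single-linkage clustering with a tolerance of one minimum
segment (two boundaries closer than a minimal segment cannot both be
real), each cluster replaced by its median. Both the tolerance and
the selection criterion are parameters of `segmentationConfig()`;
the defaults are what the rest of the package assumes.

`segmentationDiagnostics()` reports per-segment size, the absolute
PC1 difference to each neighbouring segment, and the within-segment
SD — the three quantities to examine when choosing a minimum-segment
fraction for a new data set (larger fractions give larger, smoother
segments with smaller neighbour contrasts).

# Annotation: enhancer enrichment against a ZINB permutation null

A bin is an *enhancer bin* when its Z-score is ≥ 1 **simultaneously**
on both designated mark tracks (by default H3K27ac and ATAC — jointly
acetylated and accessible; Z ≥ 1 on these long-tailed log-scale
distributions corresponds to roughly the top few percent of bins).
The observed statistic per segment is its enhancer-bin count.

The null for a segment of L bins is obtained by placing an L-bin
interval uniformly at random across the genome (chromosome chosen
with probability proportional to its number of valid start
positions, so placement is uniform over all genome-wide positions;
intervals never straddle chromosomes) 1000 times and recording each
placement's enhancer-bin count. Because enhancer bins are sparse and
spatially clustered, these background counts mix a large atom at
zero with an overdispersed positive component; a zero-inflated
negative binomial,

```
P(0) = π + (1 − π)·NB(0; μ, θ),   P(k) = (1 − π)·NB(k; μ, θ)  (k > 0),
```

fits them well, and `compareBackgroundModels()` makes the comparison
against NB, Normal and zero-censored (Tobit) Normal alternatives
explicit via AIC. The ZINB is fitted by maximum likelihood with π on
the logit scale and μ, θ on the log scale (L-BFGS-B from three
starting points; convergence reported honestly). The p-value is the
exact upper tail P(X ≥ observed) of the fitted ZINB; the enrichment
score is `log2((obs + 1)/(exp + 1))` with `exp` the empirical mean of
the background counts, so "positive enrichment" is exactly
"more than expected" and the pseudocount guards empty segments. A
segment is **enhancer-enriched** iff p < 0.05 *and* enrichment > 0 —
under heavy zero inflation an observation below its expectation can
still be in the 5% tail, and the joint rule keeps such segments out.
P-values are raw by default (each segment is tested against its own
null); an optional BH-FDR flag is available. Degenerate all-zero
backgrounds return π = 1, and positive observations are then capped
at p = 1/n_shuffles rather than 0.

Since the placement distribution depends only on segment length,
backgrounds are cached per distinct length within one
`annotateSegments()` call. Shuffling is genome-wide uniform by
default, with a chromosome-matched mode behind a flag.

# Contact integration and PTC calling

Only intra-chromosomal contacts are scored: segment pairs farther
apart than 2 Mb are skipped entirely, because normalized contact
density decays steeply with distance and distant pairs pool too few
contacts for a stable median. Segment distance is the gap between
the closer ends (0 when adjacent) — the most permissive reading —
with midpoint distance available behind a flag. For every remaining
pair (including each segment with itself) the pooled statistic is
the *median* of all contributing contact scores.

The binarization cutoff is estimated by permutation: segment
coordinates are re-placed at random (same lengths, same placement
rule as the annotation shuffles) 100 times, the interaction table is
rebuilt each time, and for every candidate cutoff c the objective is
`N_true(c) − mean_perm N_rand(c)`, the number of real entries passing
minus the expected number under randomized geometry. The returned
cutoff is the argmax, ties broken toward the smallest cutoff; with
several conditions the per-condition objectives can be averaged
before the argmax. The default candidate grid is the integers
spanning the observed score range. When contact scores come from an
external per-contact normalizer, a cutoff already established on
that score scale may be supplied directly instead; the package also
ships `fallbackScoreContacts()`, a distance-decay observed/expected
normalizer (`log2((obs + 1)/(exp_d + 1))` against the genome-wide
mean count at each bin distance) for raw contact pairs — its scores
are on their own scale, so the cutoff must then always be
re-estimated.

PTCs are connected components of the graph whose nodes are
enhancer-enriched segments and whose edges join pairs with median
score ≥ cutoff (inclusive) within 2 Mb. A segment whose
*intra*-segment median passes the cutoff qualifies as a singleton
component even without neighbours — single-segment hubs are real,
and this is the rule that admits them. Components are computed with
igraph and cross-checked in the tests against a brute-force
transitive-closure oracle.

# The synthetic fixture generator

`fixtureSpec()` describes a 15-Mb toy genome (2 chromosomes × 1500
five-kb bins) with planted truth at every level: piecewise-constant
track means (step 5 at noise SD 1, i.e. SNR 5, between 60- and
100-bin features and larger background blocks), 60-bin enhancer
regions whose bins are jointly boosted on the mark tracks at density
0.9, and three 3D hubs of 2–3 enhancer regions within 2 Mb of each
other whose bin pairs score Normal(20, 1) against a Normal(0, 1)
distance-decaying background. One enhancer region and one elevated
segment are deliberately left out of any hub so the "Enhancer" and
"Active" downstream categories are populated. `noSignalFixtureSpec()`
removes all enhancer regions and hubs as a negative control.

Tracks use Gaussian noise truncated at zero rather than read-level
counts: this keeps every planted quantity analytic (the expected
boundary positions, enhancer-bin Z-scores and pair medians can all be
computed by hand) and the fixture tiny; a Poisson mode exists for
read-count-like realism. What the fixture does **not** emulate:
mappability and copy-number artifacts, GC bias, the heavy tails and
long-range correlation of real coverage, unbalanced library depths,
and realistic Hi-C matrix structure (TADs, compartments, the full
distance-decay spectrum). Passing the planted-truth tests therefore
demonstrates the pipeline's statistical machinery end to end — exact
changepoint optimization, calibrated ZINB tails, correct pooling and
clustering — not performance on any real genome.

`evaluateBoundaryRecovery()` and `evaluateHubRecovery()` score a run
against the planted truth (boundary displacement in bins;
member-set Jaccard between each planted hub and its best-matching
PTC, mapping each planted region to the called segment that overlaps
it most).

# Downstream categories and candidate genes

Segments split into four disjoint categories: **Condensate**
(enriched, in a PTC), **Enhancer** (enriched, in no PTC), and the
enhancer-depleted remainder split into **Active** versus
**Repressed** by the sign of mean PC1 — PC1 is oriented positively
with the activity tracks, so above-zero depleted segments are active
but enhancer-poor. The zero threshold is exposed as a parameter; the
sign rule is this package's operational definition of the latter two
categories. Per-category gene lists require a gene to overlap
segments of exactly one category ("exclusively"), which makes the
four lists pairwise disjoint by construction.

Candidate genes within PTCs are selected per condition by three
filters: gene span overlaps a PTC span (overlap, not containment —
the permissive reading), TPM > 0, and a promoter window (TSS ± 5 kb,
strand-aware when strand is available) overlapping at least one
enhancer bin, the joint mark call standing in for "accessible and
acetylated". Across an ordered condition series, the candidate flag
marks genes passing in every condition after the first but not in
the first — the "acquired during the process" pattern.

# Numerical and scale choices

* Problem sizes in the shipped tests and acceptance script: 1500-bin
  chromosomes, 1000 background shuffles per segment length, 100
  cutoff permutations, 50–100 replicate simulations per statistical
  property. These match the defaults the methods were designed
  around while keeping a full run on a laptop in minutes.
* All stochastic steps (shuffles, permutations, fixtures) consume the
  R RNG; callers seed once with `set.seed()` (the pipeline driver and
  CLI take an explicit `--seed`). Identical seeds give byte-identical
  output tables.
* Exact DP ties in RSS are broken by the DP scan order and BIC ties
  toward fewer breaks; both are deterministic.
* Degenerate inputs are first-class: constant tracks are rejected by
  name at the Z-score step; windows shorter than two minimal segments
  warn and return no breaks; all-zero backgrounds yield π = 1 with
  capped p-values; empty contact files load with a warning.

# Known limitations

* The sliding-window DP sees at most one window of context, so breaks
  spaced further than a window apart are never traded off against
  each other (the same trade-off the window approach always makes).
* One ZINB is fitted per segment *length*, not per segment location;
  chromosome-level composition differences are only captured in the
  optional chromosome-matched mode.
* Inter-chromosomal hubs are out of scope by design.
* The fallback contact normalizer is a simple distance-decay
  observed/expected ratio — adequate for cutoff-relative analysis on
  one data set, not a substitute for a dedicated per-contact
  normalizer when comparing conditions.
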