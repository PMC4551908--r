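---
title: "Three-component analysis of paired longitudinal omics"
author: "threeCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-component analysis of paired longitudinal omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threeCA)
```

# The problem

Serially sampled ("paired longitudinal") designs assay the same subject at two
time points, so every contrast is intra-individual and inter-personal baseline
variation cancels. Such cohorts are rare and small — ten subject pairs is a
realistic size — and at that scale classical per-feature tests retain almost
nothing after multiple-testing correction. threeCA implements a deterministic,
rank-based alternative: each feature is summarised by three geometric
components of its pair-point cloud, the components are aggregated into one
score, a standard-deviation rule picks a high-confidence selection, and the
directionality of whole gene sets is then assessed with pre-ranked gene set
enrichment analysis (GSEA) on the signed temporal component.

# The model

For a feature, subject pair $i$ contributes a point
$p_i = (x_i, y_i)$ with $x_i$ the early and $y_i$ the late intensity on the
working scale. With centroid $c = (\bar{x}, \bar{y})$:

* **variance radius** $v = \sqrt{\tfrac{1}{n}\sum_i \lVert p_i - c\rVert^2}$ —
  the root-mean-square distance of the pair points from their centroid, a 2-D
  standard-deviation radius measuring inter-individual variability;
* **signal strength** $s = \lVert c \rVert$ — the centroid's distance from
  the origin, guarding against low-intensity artifacts;
* **temporal distance** $t = (\bar{y} - \bar{x})/\sqrt{2}$ — the signed
  perpendicular distance of the centroid from the 45° identity line (the null
  of "no change"); positive $t$ means an increase with time.

$|t| \le s$ always (a perpendicular distance to a line through the origin
cannot exceed the distance to the origin), and $v = 0$ exactly when all pair
points coincide.

The verbal definition of the variance component ("minimum distance over all
pairs, a radius approximating the variance") admits several estimators; we
use the RMS radius because it is smooth, has an exact brute-force oracle, and
degenerates nowhere, whereas a literal nearest-point distance is frequently
zero. The combination rule is likewise declared openly: each component is
ranked across features (variance ascending, signal descending, $|t|$
descending, average ranks on ties) and the score is the *equal-weight mean of
the three ranks*, lower = more significant. Rank aggregation is scale-free —
essential when the same machinery must serve RPKM-like intensities and binned
log2 ratios — and equal weights encode the absence of any prior preference
among the components; `combineScores()` exposes the weights so informed
reweighting remains possible. Both choices sit behind the
`computeComponents()` / `combineScores()` boundary so an alternative
formulation can be dropped in without touching anything downstream.

## Working scale

For linear-scale inputs the components are computed on
$\log_2(x + \text{pseudocount})$ with pseudocount 1 by default; log stabilises
the variance radius across the intensity range and matches the log2-ratio
scale of tiling-array windows, making scores comparable across data types.
Raw-scale computation is available (`logTransform = FALSE`). The pseudocount
compresses differences for features whose intensity is near or below 1; that
is intentional (such features are low-confidence) but worth remembering when
interpreting recall.

## Selection rule

Scores are transformed to $z = (\text{score} - \min \text{score})/\text{SD}$
(sample SD, $n-1$ denominator — fixed so results are reproducible) and
features with $z \le k$ are selected, $k = 1$ by default. The feature
attaining the minimum is always selected. On rank-aggregated scores this rule
selects a few percent of features; the table's metadata reports the fraction
selected and whether the lowest-scoring 2% fall entirely inside the
selection, which is the expected behaviour at genome scale and is checked on
every run. The "top 2%" quantity is a reported diagnostic, not a second
selection rule.

## Component contribution

To diagnose what drives a feature's score, ranks are inverted
($\text{invrank} = N + 1 - \text{rank}$) and expressed as percentages summing
to one. A feature ranked identically on all three components contributes
exactly $(1/3, 1/3, 1/3)$ — an analytic identity the test suite asserts.
Comparing top-scored features against random features and against a
shuffled-pairing control (`shuffledControl()`, which permutes the $2n$ sample
columns into pseudo-pairs, preserving marginals while destroying the
longitudinal pairing) shows whether the selection is biased toward any single
component.

# Coupling with pre-ranked GSEA

The combined score ranks features but its sign-free components cannot say
whether a *set* moves up or down. The signed $t$ of each gene is therefore
used directly as a ranked-list metric (RNK semantics). Two usage modes exist:

* `selectedOnly = TRUE` (the guided mode): the list is restricted to the SD
  selection, i.e. to temporal changes bounded by an upper limit on the
  variance. Because selected genes have extreme $|t|$ by construction, set
  members concentrate at the edges of the enrichment plot.
* `selectedOnly = FALSE`: the full gene list.

`gseaPreranked()` is self-contained: the weighted Kolmogorov–Smirnov running
sum (hit increment $|m_i|^p/N_R$, miss decrement $1/(N - N_{hits})$, default
$p = 1$), a gene-label permutation null (random same-size subsets of the
universe; permutations are shared across sets of equal size, which leaves the
null distribution unchanged and saves work), NES normalisation by the mean
magnitude of same-sign permutation scores, nominal p from the same-sign tail
with a +1 correction (never exactly zero, floored at $1/(n_{perm}+1)$), and
the NES-pooling FDR of the reference GSEA implementation (`fdrMethod = "BH"`
switches to Benjamini–Hochberg). Defaults mirror the reference tool
(`nPerm = 1000`, `minSize = 15`, `maxSize = 500`); for guided runs the
universe is only a few hundred genes, so `minSize` should be lowered (we use
5 or less in guided analyses) — at the default it can silently drop every
set.

Numerical conventions that matter for reproducibility: metric ties in the
ranked list are broken lexicographically by gene symbol (ES depends on
order); when the maximum positive and negative deviations of the running sum
tie in magnitude the ES is defined as 0 — exact ties genuinely occur, because
deviations attained before the first or after the last hit are pure multiples
of the miss decrement — and the tie is detected with a $10^{-12}$ relative
tolerance so that the outcome cannot depend on floating-point summation
order. This is the convention of the widely used implementations and the only
rule antisymmetric under negating-and-reversing the list, an invariant the
test suite checks on hundreds of random instances.

`wilcoxonSetShift()` provides the complementary set-level location test of a
set's score distribution against background (exact null up to combined
$n = 25$ without ties, normal approximation with tie correction otherwise;
all-tied input returns $p = 1$).

# Baseline paired statistics

`buildPairing()` + `intraVsInterTest()` implement the comparison the rank
score is measured against: per feature, intra-individual changes (late −
early per subject, log scale) are tested against inter-individual changes
between age-matched subjects (age difference ≤ 2 years by default, pairs
oriented older-minus-younger, lexicographic subject order on exact-age ties),
with BH correction across features. The inter background uses early samples
by default — a cross-section uncontaminated by the second sampling —
switchable to late or both. The default test is the Wilcoxon rank-sum
(robust at $n = 10$); Welch's t is available. Note the rank-sum's type-I
error is only defined when intra and inter changes are exchangeable under
the null; with gene-specific inter-individual baseline spread the two groups
differ in scale even without temporal effects, so calibration checks use an
exchangeable configuration (inter-individual sd 0). Under that null on 5,000
genes the empirical rejection rate at $\alpha = 0.05$ matches the exact
attainable level of the discrete test, and after BH correction essentially
nothing is discovered — the expected behaviour of per-feature testing at
this sample size, and the motivation for the score-based approach.
`fisherEnrichment()` supplies generic one-sided over-representation tests of
a selection against annotation sets.

# Tiling-array preprocessing

`binProbes()` averages probe log2 ratios in 500 bp windows with 250 bp step
(defaults), anchored at position 0 of each chromosome; a probe belongs to a
window when its midpoint lies in the half-open window interval (midpoint
membership avoids double-counting long probes; the step may not exceed the
window, which would leave gaps). Windows with fewer than 4 probes are marked
`kept = FALSE`. `quantileFloor()` then resets member ratios below the
track-wide 50% quantile to that quantile and discards windows with none or
one probe strictly above it — low ratios after normalisation include cases
where input exceeds enrichment and carry no signal. The floor quantile is
computed track-wide (it is a global normalisation floor, not a per-window
statistic) with the inverse-CDF (type 1) definition, i.e. an order
statistic: this makes the operation exactly idempotent, which an
interpolated quantile is not. "Above the floor" is strict; ties at the floor
count as not above. Internally coordinates are 0-based half-open; BED input
is converted on read.

Binned windows scored with `computeComponents()` can be stratified by
distance to CpG islands with `cgiDistancePartition()`: windows overlapping
an island form the distance-0 stratum, shore windows are binned in 250 bp
increments starting at the island boundary using whichever window edge is
closer to the nearest island, and per-stratum summaries of the component
values are returned. Islands are merged and length-filtered (≥ 500 bp by
default) on read.

# The synthetic study generator

`simulationConfig()` / `simulatePairedExpression()` emulate the intended
study design: 10 subject pairs, sampling gaps uniform on 12–19 years, first
samples between 35 and 75 minus the gap years of age, lognormal intensities
(per-gene baseline $\log_2$ level $\sim N(5, 2)$), gene-specific
inter-individual sd drawn as $|N(0, 0.5)|$, per-sample measurement noise sd
0.25, and disjoint planted sets with signed log2 effects (the reference
planted study uses one 100-gene set at effect −1). The generative model is
Gaussian on the log scale: subject baseline effects are shared between the
two time points (`pairedBaseline = TRUE`), which is precisely the strength
of a longitudinal design — baseline variation cancels from the change. A
high-variance regime (`pairedBaseline = FALSE`, inter-individual scale 1.5)
draws the subject effect independently per time point, emulating
subject-by-time trajectory heterogeneity; only in such a regime can
inter-individual variance contaminate the temporal component, and it is
there that variance-bounded pre-filtering before GSEA demonstrably
strengthens enrichment (the acceptance script computes the filtered and
unfiltered enrichment scores side by side). An optional intensity–variance
coupling makes low-intensity genes noisier, exercising the rationale for the
signal-strength component.

What the generator does **not** emulate: count-level sampling noise,
gene–gene correlation, probe sequence effects, real genome annotation, or
nonlinear age trajectories. Passing tests therefore demonstrate the
machinery's correctness and calibration under a clean Gaussian paired model,
not performance on any particular real data set.

A property worth stating plainly: planting a temporal effect moves only the
$t$ component of the affected genes — their variance and signal ranks remain
exchangeable with the background by construction. Equal-weight rank
aggregation therefore dilutes a purely temporal signal with two uninformative
ranks, and the 1-SD selection of the reference planted study recovers a
modest fraction of the planted genes (the regression test pins the reference
run's exact counts; the Fisher enrichment of the selection is significant at
roughly $p \sim 10^{-3}$). This is an honest structural property of
equal-weight aggregation under this generative model, documented rather than
tuned away; in real data, where biologically coordinated changes often also
share favourable variance and intensity profiles, the three ranks reinforce
rather than dilute each other.

`simulateProbeTrack()` provides the analogous ground-truth generator for the
binning path: uniformly placed fixed-length probes over a region, regional
truth plus Gaussian noise, matched early/late tracks per subject.

# Problem sizes and determinism

Test and acceptance runs use 5,000-gene × 10-pair matrices for
calibration/recovery, 400 random gene sets at 200 permutations for GSEA
null calibration, 1,000 permutations for reported enrichments, and 1,000
random small instances for the symmetry suite — sizes chosen to exercise
genome-scale code paths while keeping a full run in minutes on one core.
Every stochastic step (simulation, permutation, shuffling) takes an explicit
seed and restores the RNG state afterwards, so identical inputs and seeds
give byte-identical outputs; `runPipeline()` records a manifest with the
configuration, seed and artifact checksums.

# Known limitations

* Paired designs only; no cross-sectional or regression-on-age modelling.
* Pre-ranked GSEA only, with a gene-permutation null; no expression-matrix
  phenotype permutation.
* No array normalisation beyond the floor rule and a quantile-normalisation
  utility; inputs are assumed quantified and normalised upstream.
* The SD selection's size is largely structural (a few percent of features)
  rather than adaptive to signal strength — a property inherited from rank
  aggregation.
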