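---
title: "Model-based RSA of two-stage category dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based RSA of two-stage category dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsadyn)
```

## The scientific problem

Face pareidolia -- seeing illusory faces in inanimate objects -- poses a
representational question: when the visual system processes a pareidolia
image, is its neural representation closer to that of real faces or to
that of the matched objects, and does the answer change over processing
time (or, in a feed-forward network, over layers)?

`rsadyn` implements the analysis machinery for answering that question
with representational similarity analysis (RSA). The pipeline's currency
is the representational dissimilarity matrix (RDM): a symmetric,
zero-diagonal matrix of pairwise correlation distances between response
patterns to a fixed, ordered stimulus set (here faces, pareidolia images,
and matched objects, canonically 32 of each).

## The model and its components

**Idealized hypothesis RDMs.** Two binary RDMs encode the competing
hypotheses. Both set within-category dissimilarity to 0 and face--object
dissimilarity to 1. They differ on the pareidolia blocks:
*pareidolia~faces* sets face--pareidolia pairs to 0 and
pareidolia--object pairs to 1; *pareidolia~objects* reverses this. With
the balanced 32/32/32 design the two model vectors (4,560 pairs) overlap
substantially -- their Spearman correlation is the phi coefficient of the
block counts, about 0.092 -- which is exactly why partial correlation is
needed to separate their contributions.

**Partial Spearman correlation.** All comparisons are rank-based. For a
data RDM vector $y$, a model vector $x$ and covariate vectors $z_i$, all
vectors are rank-transformed (average ranks; ties are routine in binary
models), $x$ and $y$ are residualized on the covariate ranks plus an
intercept by least squares, and the Pearson correlation of the residuals
is returned. With no covariates this is exactly Spearman's correlation.
We implement partialling by residualization rather than the recursive
first-order formula: for one covariate the two are algebraically
identical (the test suite asserts agreement to 1e-10), and
residualization generalizes to the two-covariate case the commonality
index needs.

**Time-wise and layer-wise profiles.** The partial correlation of each
hypothesis RDM (controlling the other) is computed against each subject's
RDM at every time point, or against each layer's RDM in a network
hierarchy. Degenerate time points yield missing values rather than being
dropped, preserving the time axis.

**Commonality index.** For a neural RDM $N$, a model-system RDM $S$
(e.g. a penultimate network layer) and target hypothesis $T$ with
competitor $O$:

$$ c_T = r^2(N, S \mid O) - r^2(N, S \mid T, O) $$

the unique share of the $N$--$S$ alignment attributable to $T$. We
implement exactly this difference of squared partial correlations; richer
variance-partitioning decompositions exist, but the two-model difference
is the quantity the analysis needs. Negative values (suppression) are
reported unclipped -- truncation would bias group means toward zero.

**Group inference.** The sign-flip cluster permutation test treats each
subject's whole correlation (or difference, or commonality) time course
as the exchangeable unit: under the null the group mean is zero at every
time, so each permutation multiplies every subject's course by a random
sign. The cluster-forming threshold at each time point is the 95th
percentile of that time point's permutation distribution of the absolute
group mean (two-sidedness via the absolute value; the per-time threshold,
rather than a pooled one, follows the description of a distribution per
time point). Clusters are maximal runs of supra-threshold points scored
by their *length* in contiguous time points -- not by summed mass -- and
cluster p-values use the add-one estimator so p is never exactly zero.
If more permutations are requested than the $2^{n}$ possible sign
assignments, the test enumerates them exhaustively.

**Noise ceiling.** Per time point, the upper bound is the mean over
subjects of the Spearman correlation between each subject's RDM vector
and the all-subject mean vector; the lower bound uses the leave-one-out
mean. Spearman (not Pearson) is used so the ceiling is on the same scale
as the pipeline's comparison statistic.

**Stimulus bootstrap and permutation tests.** Layer-wise statistics get
SEMs by resampling stimuli with replacement (1,000 replicates by
default); on each replicate, off-diagonal pairs formed by two copies of
the same original stimulus are excluded before correlating, since their
dissimilarity is identically zero and would inflate the statistic.
Replicates with fewer than 10 valid pairs (or a degenerate vector) are
rejected and redrawn. Significance uses stimulus-label permutations of
the data RDM (simultaneous row/column shuffles; 10,000 by default),
two-sided add-one p-values, Bonferroni-corrected with a family size
defaulting to layers x models (the reported family; the correction is
stated without a family size in the literature this follows, so the
factor is caller-overridable). Because a row/column permutation only
re-indexes the off-diagonal entries, ranks are computed once and
re-indexed per permutation -- bit-identical to re-ranking, much faster.

**Occlusion attribution.** A window slid with a fixed stride is replaced
by a baseline intensity and the drop in the class score recorded;
a pixel's attribution is the mean drop over all windows covering it, so
positive values mark class-supporting features. Averaging (not summing)
keeps the scale stride-independent; edge positions are clamped to the
border so every pixel is covered. Window 40 px and stride 20 px on
400 x 400 inputs are the defaults (the source analysis leaves them
unspecified); the baseline defaults to the image's mean intensity. The
mask score is the fraction of pixels in a region mask with strictly
positive attribution.

## The synthetic-data generators

The pipeline is exercised end to end on generated data with the planted
structure the analyses assume.

**Subject RDM series.** Ground truth is
$D(t) = b + w_F(t)\,M_F + w_O(t)\,M_O$ with Gaussian weight bumps peaking
at 165 ms (face-likeness) and 255 ms (object-likeness) -- the two-stage
dynamics the analysis is designed to resolve -- and width 50 ms, a value
that makes the two bumps overlap substantially (peaks 90 ms apart) so
peak separation is a non-trivial recovery problem. Defaults: 22 subjects,
32 stimuli per category, -100..1000 ms in 5 ms steps (221 points),
amplitudes 1, baseline 1.5, noise sd 0.5. Noise is additive on
upper-triangle dissimilarities (then symmetrized, diagonal re-zeroed,
clipped at zero): it realizes directly the statistical structure the RSA
stage assumes. A pattern-level (sensor-space) generator would be the
natural extension seam but is not what these analyses consume. The
baseline of 1.5 keeps expected zero-clipping below 0.1% at the default
noise; configurations whose expected clipping exceeds 1% are rejected
rather than silently distorted. An optional sustained late plateau on the
object weight is available but defaults to 0, so the recoverable ground
truth is exactly the two peak latencies. Amplitude 1 against noise sd 0.5
puts single-subject peak partial correlations around 0.4 and group means
around 0.7 -- comfortably detectable but far from saturated.

**Layer features.** Each layer draws three category base patterns from an
orthonormal zero-mean basis mixed by the Cholesky factor of a target 3x3
correlation matrix $1 - s\,(w_F M^3_F + w_O M^3_O)$, so at zero scatter
the sample Pearson RDM is an *exact* affine image of the scheduled model
mixture (a deliberate construction: it makes the zero-noise test an exact
identity rather than an approximation). The default schedule moves
face weight 0.8 to 0.2 and object weight 0.2 to 0.8 across 15 layers.
Note a structural fact the tests respect: rank correlations on
block-constant geometry respond to the *ordering* of the three
cross-category values, so layer profiles are step-like and (weakly)
monotone in the schedule rather than proportional to it.

**Saliency fixtures.** Strictly positive random images with rectangular
Face/Eyes/Mouth masks (Eyes and Mouth disjoint inside Face, OutsideFace
the complement) and a linear scorer whose face-class weights live only in
the Eyes (object-class weights only outside the face). For a linear
scorer with nonnegative weights, baseline 0, and a strictly positive
image, a pixel's attribution is positive exactly when some covering
window overlaps the scorer's support -- so expected mask ratios follow
from window-coverage geometry alone, independently of the occlusion code
path, and serve as the oracle.

**What passing these tests does and does not show.** The generators plant
precisely the structure the analyses assume: additive dissimilarity
mixtures, Gaussian noise, block-exact model geometry, linear scorers.
Recovery on them validates the machinery -- the statistics, their
calibration, and the code -- not the empirical claims about brains or
trained networks, which require the original recordings and networks.
Real MEG RDM series have autocorrelated, non-Gaussian noise and
condition-dependent reliability; real network RDMs are not affine images
of category templates; real classifiers are nonlinear, so the closed-form
saliency oracle does not transfer. The analyses make none of these
assumptions (rank statistics and permutation inference are
distribution-free); only the *generators* do.

## Numerical choices

- Upper-triangle vectorization is row-major over pairs (i < j), frozen,
  and shared by every correlation in the pipeline.
- Ties: average ranks everywhere.
- Correlation distances are snapped to exact 0 / 2 when within 1e-12 of
  those endpoints, so identical patterns stay exactly tied under ranking
  (float dust otherwise breaks tie structure and caps Spearman
  correlations just below 1).
- Residual vectors with sum of squares below 1e-12 x length are treated
  as degenerate (error in direct calls; missing value inside time-course
  loops).
- Classical (Torgerson) MDS, via `stats::cmdscale`, rather than iterative
  stress majorization: deterministic up to rotation/reflection, which
  keeps the embedding testable; rank-deficient geometries are padded with
  zero axes.
- Every stochastic operation takes an explicit integer seed; regeneration
  is bit-identical. Cluster p-values and permutation p-values use add-one
  estimators, so they lie in (0, 1].

## Problem sizes in the shipped analyses

The numbered scripts under `analysis/` run a 12-subject, 48-stimulus
cohort and scaled resampling counts (200 bootstrap replicates, 1,000
permutations) so the full workflow completes interactively; the test
suite's calibration checks use 200 null datasets with 512 sign
permutations or 500 stimulus permutations, and the recovery checks use 50
full-scale cohorts (22 subjects, 96 stimuli, 221 time points). These
sizes are the package's choices for routine verification; all counts are
arguments, and the literature-standard defaults (1,024 sign flips, 1,000
bootstraps, 10,000 stimulus permutations) are what the functions use when
not told otherwise.

## Known limitations

- Only the two correlation distances are implemented (no Euclidean or
  crossnobis RDMs), and only two-class occlusion attribution.
- The commonality implementation is the two-model difference form; it
  does not produce full Venn decompositions over three or more models.
- Sign-flip inference assumes subjects are exchangeable and their time
  courses mean-zero under the null; it is a temporal-cluster test only
  (no sensor-space or spatiotemporal clustering, no TFCE).
- The noise ceiling follows the subject-vs-mean convention; other
  conventions (e.g. Kendall's tau-a against the best fixed model) give
  different absolute levels.
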