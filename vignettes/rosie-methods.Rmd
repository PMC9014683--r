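---
title: "Robust sparse ensemble methodology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust sparse ensemble methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosie)
```

## The problem

In binary-labelled transcriptomic data the number of features (genes)
far exceeds the number of samples (n << p), so classifiers must be
*sparse*, and a handful of atypical samples — mislabelled cases,
technical artifacts, biologically divergent tumours — can dominate any
non-robust fit.  `rosie` addresses both at once: three inherently
different robust sparse classifiers are fitted independently, each
produces (i) a set of selected features and (ii) a per-sample
outlyingness ranking; the rankings are fused by the rank product
statistic into consensus *influential sample* calls, and features are
selected by three-way intersection.  Because the members rest on
different assumptions (a PLS-type discriminant, an unsupervised trimmed
clustering, a trimmed penalized likelihood), a sample must look atypical
from several angles before the consensus flags it.

## The three ensemble members

### SPRM-DA (`fit_sprm`)

Sparse partial robust M-regression discriminant analysis.  The 0/1
response is encoded as centered group codes (class 1 &rarr; `n0/n`, class 0
&rarr; `-n1/n`, symmetric about zero), features are standardized by
column median and MAD (MAD floored at 1e-8 so near-constant features
survive), and a weighted sparse NIPALS PLS is iterated to a fixed point:

1. weighted PLS directions with soft-thresholding at `eta * max|v|`
   per component — `eta` in [0, 1) controls sparsity;
2. case weights recomputed from standardized residuals (`w_r`) and from
   robust score-space leverage (`w_x`) with the Fair weight function
   (tuning constant 4 by default); `case_weight = w_r * w_x`.

The case weight is the method's inherent robustness measure, so the
outlyingness score is `1 - case_weight`.  Prediction assigns the nearest
case-weighted class centroid in score space; exact midpoints go to
class 0.

Numerical notes.  The reweighting map is non-smooth (median/MAD jumps),
and on small fixtures it can settle into a small period-2 limit cycle
rather than a point; the update is therefore damped (new weights
averaged with the previous ones — same fixed points) and convergence is
declared on the norm-relative coefficient change with `tol = 1e-4`.
When `max_iter` is exhausted the last iterate is returned with
`converged = FALSE` and a warning; cross-validation loops score such
iterates silently, which is standard practice for IRLS-type tuning.
With `eta = 0` and the `"unit"` weight function the fit reduces exactly
to PLS1 regression (verified in the tests against an independent
Krylov-basis closed form).

On clean Gaussian data the Fair(c = 4) weights of typical samples land
around 0.5–0.75, not near 1: both `w_r` and `w_x` penalize the typical
standardized deviation of ~0.67.  Outlyingness is therefore meaningful
only relatively, which is all the rank-based consensus consumes.

### RSKC (`fit_rskc`)

Robust sparse K-means with K = 2: alternating (a) trimmed Lloyd steps in
the feature-weighted metric, trimming the `ceiling(alpha * n)` cases with
the largest weighted distance (`O_W`); (b) a second trim in the
*unweighted* metric (`O_E`) with center updates on untrimmed cases —
this catches outliers hidden by near-zero feature weights; and (c) a
feature-weight update maximizing the weighted between-cluster sum of
squares subject to `||w||_2 <= 1`, `||w||_1 <= s` (soft-thresholding, with
bisection on the threshold).  Restarts draw K distinct initial samples
*by sorted sample ID*, so the fit does not depend on row order.

The outlyingness score is the weighted squared distance to the nearest
center — the quantity the method trims on — computed for every sample,
trimmed or not.  The monitored objective is non-decreasing when
`alpha = 0`; with trimming the trimmed subset changes between iterations
and small dips (observed below 0.1%) are possible, which is a property
of the published trimmed scheme, not of this implementation.  With
`alpha = 0`, `s = sqrt(p)` and weights held uniform the fit reduces to
Lloyd's K-means (verified against `stats::kmeans`).

Cluster labels are mapped to classes by whichever of the two possible
mappings minimizes misclassification (ties: identity), which is needed
only for reporting misclassification counts — the method itself never
sees the labels.

### enetLTS (`fit_enetlts`)

Elastic-net penalized logistic regression over the best h-subset
(`h = ceiling(h_fraction * n)`, default 0.75): many small class-stratified
elemental starts (3 per class) are fitted and improved by concentration
steps — fit on the current subset, recompute deviance residuals on all
n, keep the h cases with the smallest deviance (class-stratified so no
subset degenerates) — which cannot increase the trimmed penalized
objective; the best starts get C-steps to a fixed point.  The penalized
solves use glmnet.  A reweighting step then refits on all cases whose
standardized Pearson residual is below the 0.9875 normal quantile.
Outlyingness scores are absolute standardized Pearson residuals of the
final (reweighted) fit; the reweighted rather than raw fit is used
because it is the better estimate of the clean-data model.  With
`h_fraction = 1` and vanishing lambda the method collapses to the
ordinary logistic MLE (verified against `glm`).

## The rank-product consensus (`consensus_outliers`)

Each method's scores are ranked with rank 1 = most outlying, ties
averaged (ranks always sum to `n(n+1)/2`).  The consensus statistic is
`RP(i) = prod_l R_l(i)` over the k = 3 rankings.  The p-value is the
*exact* tail probability under the discrete-uniform null (ranks
independent uniform on {1..n}):

`P(prod U_l <= rp) = #{(a1..ak) in {1..n}^k : prod a <= floor(rp)} / n^k`

computed by capped divisor counting — O(n^2) vectorized operations for
k = 3, milliseconds at n ~ 1000.  This null deliberately ignores the
without-replacement dependence within a ranking, which is the
convention of the rank-product test; a calibration test confirms ~5% of
null samples fall below p = 0.05.  Tie-averaged (fractional) rank
products are handled by real-valued thresholding, which coincides with
counting up to `floor(rp)`.  A gamma (continuous-limit) approximation is
available behind `method = "gamma"` for large k; it is accurate in the
distribution bulk and not in the far discrete tail, which is exactly
where the exact count is cheap.

q-values are Benjamini–Hochberg by default; a Storey-type option
(fixed-lambda pi0 estimate at lambda = 0.5) is provided because
published consensus tables of this kind are often computed with
pi0-adaptive estimators and are not exactly reproducible by BH alone.
Samples with `q < 0.05` are called influential.

## Hyperparameter optimization (`optimize_hyperparameters`)

* SPRM: grid over `n_components x eta`, stratified 5-fold CV
  misclassification; ties resolve toward the sparser model.
* enetLTS: internal 5-fold stratified CV of trimmed deviance on the
  final subset over `alpha_mix x lambda`; ties toward larger penalty.
* RSKC: the L1 bound by the permutation gap statistic (real objective
  vs. column-permuted data, 25 permutations by default); `alpha` by
  maximal agreement of mapped cluster labels with the supervised
  members' predictions (the unsupervised member never sees true labels).

All choices are deterministic given the seed.  Grid defaults are small
on purpose; they are reconstructions, not published values, and every
entry is user-overridable through `rosie_control()`.

## Bootstrap validity check (`run_validity_check`)

Stratified block bootstrap with m = 5 blocks by default: samples are
partitioned per class into m near-equal parts (per-class sizes differ by
at most one; remainder parts are assigned from a seeded shuffled queue
shared across classes, so extras spread over blocks before any block
receives two), then each block is refilled to size n by class-stratified
sampling with replacement.  Every sample therefore appears in at least
one block and every block carries the original class counts exactly.
Duplicates are kept as genuine multiset members, and block consensus
p-values use the block size as n with duplicates counted individually —
the bootstrap-natural choice.  Blocks are refitted with the main run's
hyperparameters (never re-optimized), and the report tallies per
influential sample (blocks present / re-flagged) and per common feature
(blocks re-selected).

## Simulation study (`run_simulation_study`)

The generator emulates a bulk expression study after preprocessing:
200 samples, 3200 features, balanced classes, unit-variance Gaussian
noise, and a sparse signal — 5% of features shifted by 1.0 SD in class 1.
The signal density and effect size are this package's own defaults
(chosen so the supervised members operate in a strong-but-not-saturated
regime); all four parameters are exposed.  Three contamination
scenarios: labels switched for 5% or 15% of samples (matrix untouched),
or 5% of samples shifted by 3 per-feature SDs on 15% of features
(labels untouched; SDs computed on the uncorrupted matrix over all
samples, as nothing indicates class-conditional scaling).  Scenario
replicates run under the fixed `simulation_control()` settings so AUCs
are comparable across seeds.

What the generator does *not* emulate: count-distribution artifacts,
heteroscedastic (mean-dependent) noise, correlated gene modules, batch
structure, or overlap between corrupted and informative features
(corruption picks features uniformly).  Passing tests therefore show
correct and robust behaviour of the algorithms under idealized sparse
Gaussian signal, not performance guarantees on any particular real
dataset.

Rankings are evaluated by ROC/AUC against the planted truth, with ties
handled by threshold grouping (AUC equals the concordant-pair
probability with half-weight ties).  The consensus is scored as
`-log RP`: identical ordering to the p-value for integer ranks and
cheaper.  Under the defaults the characteristic regime is: supervised
members near-perfect and RSKC near 0.5 on label switches, RSKC dominant
and enetLTS near or below 0.5 on expression shifts, and the consensus
best on average across scenarios — the behaviour the ensemble is built
to deliver when the contamination type is unknown a priori.

Problem sizes in the shipped tests and the acceptance script use
p = 800 (with the same 5% signal density); the regime above is stable
in p and this keeps a full multi-seed study in the minutes range on a
single CPU.

## Degenerate inputs and edge rules

* Exact centroid midpoints predict class 0 (SPRM); fitted probability
  exactly 0.5 predicts class 1 (enetLTS); cluster-mapping ties keep the
  identity mapping (RSKC).  All three are arbitrary but documented and
  tested.
* Constant features: dropped by `drop_constant_features`; inside SPRM
  the MAD floor keeps near-constant survivors finite.
* Empty cluster after trimming: the restart is discarded; the fit
  errors only if every restart fails.
* A failed ensemble member aborts `run_rosie` naming the member — the
  consensus is defined for exactly three rankings, so there is no
  silent two-method fallback.
* `log_transform` is log2(x+1) — the usual convention for FPKM-type
  abundances — configurable in base and offset, and refuses negative
  input naming the offending cell.
* The per-feature AUC filter symmetrizes importance as
  `max(AUC, 1-AUC)`, is rank-based (hence invariant under monotone
  transforms), and breaks ties at the cut by original feature order.
  The retained feature count is a free parameter: the upstream
  restriction that motivates pre-filtering in real cohorts is not a
  property of this package.

## Known limitations

* The three members are reconstructions of the published algorithm
  families built on their primary literature; no numerical replication
  of any specific R package's internals is attempted or claimed.
* The exact q-value algorithm behind published consensus tables of this
  kind is not identifiable from rank data alone; BH and the Storey
  option bracket the reasonable choices, and influential calls at
  q < 0.05 should be robust to the choice (both are monotone in p).
* K > 2 clustering, a pluggable fourth member, and permutation-based
  rank-product nulls are out of scope in this version.
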