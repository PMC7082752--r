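---
title: "Affective spaces, cluster dispersion and personality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affective spaces, cluster dispersion and personality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(affectspace)
```

## The analysis in one paragraph

An *affective space* is a geometric representation of emotional
stimuli in which inter-item distance encodes subjective emotional
dissimilarity.  In the multi-arrangement task, a participant
repeatedly drags subsets of items around a circular on-screen arena;
the adaptive *lift-the-weakest* rule keeps presenting the item subsets
about whose mutual distances the least evidence has accumulated.
Inverse multidimensional scaling (inverse MDS) fuses the partial 2D
arrangements into a full item-pair dissimilarity matrix (DSM) per
participant, vectorized as a DSV.  After scaling each DSV to [0, 1] by
its maximum, the elementwise *median* DSV across participants defines
a group space, which is clustered by complete-linkage agglomeration
and validated by the silhouette index across candidate cluster counts.
Each participant's *dispersion* of a cluster c is
median(D~c~)/|c| — the median of their within-cluster pair
dissimilarities divided by the cluster's item count — a per-person
measure of how cohesive that affective concept is.  Dispersion is then
regressed on the Big Five T-scores (N, E, O, A, C) by all-subsets OLS:
all 2^5^ − 1 = 31 predictor subsets are fit on z-scored data, the
minimum-BIC model is selected, and two Monte Carlo procedures
calibrate it — p~FWER~(all) against a null distribution of *minimum*
BICs over all 31 models on randomized outcomes, and p(same) against
the null distribution of the *selected model's* BIC on randomized
outcomes.

## The synthetic-data generator

No behavioral data ship with the package; a generator plants the
statistical structure the analysis assumes so every stage can be
validated by parameter recovery.

**Stimuli.**  `make_stimulus_set()` produces 9 categories × 6 items
(54 items, hence C(54, 2) = 1,431 pairs) with valence/arousal ratings
on the 1–9 scale drawn around fixed category prototypes.

**Traits.**  `make_trait_table()` draws T-scores (mean 50, SD 10)
from a multivariate Gaussian.  The default trait intercorrelation is
the identity: population trait correlations are an empirical question
the package does not take a stance on, and the value is configurable.

**Planted spaces.**  `make_planted_spaces()` places each item around
its cluster's centroid in a 2D latent space (valence-like axis first,
arousal-like second) with per-cluster, per-participant spread

    spread(c, i) = baseline(c) + sum_t slope(c, t) * z_i(t) + e,
    e ~ N(0, noise_sd^2),

floored at 10% of the baseline so distances stay positive.  The true
DSM is the Euclidean distance matrix of the latent coordinates.

The default geometry places four clusters at (±2.6, ±0.9): a generic
positive cluster (30 items, spread 0.25), an erotic cluster (6 items,
0.30), a fear/violence cluster (12 items, 0.18) and a medical cluster
(6 items, 0.18).  These values were chosen so that the group-median
space has a genuine two-level hierarchy: the positive/negative split
along the first axis dominates (silhouette maximum at k = 2), the
k = 3 cut — which has to break one supercluster — *dips*, and the
k = 4 cut that completes the planted partition rises again.  A fully
symmetric two-by-two geometry cannot produce this profile: with equal
subcluster separations on both sides the silhouette is monotone
across 2 → 3 → 4, because the k = 3 cut always splits whichever side
changes the profile in the same direction the k = 4 cut does.  The
dip-then-rise shape requires the asymmetry built into the defaults
(a wide erotic cluster close to the generic positive one, and two
well-separated tight negative clusters).

The default effect specification plants slopes of +0.025 (N) and
−0.025 (C) latent units per trait SD on the fear/violence cluster's
spread with spread noise SD 0.06, i.e. standardized effects of about
0.35 each that jointly explain about a quarter of the spread variance
— the magnitude regime of interest for cohort sizes near 58.

**Sessions.**  `simulate_session()` runs the adaptive protocol
against the planted DSM.  Each selected subset is placed by classical
MDS of the true dissimilarities restricted to the subset, rescaled to
fill the unit-radius arena (participants use the whole arena
regardless of the subset's absolute scale), and perturbed by isotropic
Gaussian placement noise in arena units (default SD 0.05 = 5% of the
arena radius).  The session ends when every pair's evidence reaches
the protocol threshold.

What the generator does *not* emulate: participant fatigue or order
effects, deliberate (non-Gaussian) placement strategies,
heavy-tailed or participant-specific noise, semantic structure beyond
the planted geometry, and any dependence of arrangements on image
content.  Passing recovery tests therefore show that the estimators
are correct and well-calibrated under the stated noise model, not that
real arrangement data satisfy that model.

## Evidence accounting and trial selection

Evidence for a pair accumulates by the *squared* on-screen distance
between its items each time they co-occur in a trial: larger
separations are measured more reliably relative to placement noise,
and a zero separation carries no scale information at all.  The next
trial contains the globally weakest pair; remaining slots are filled
greedily by the candidate whose pairs with the current subset have the
largest summed evidence deficit, with two tie-breaks: least
accumulated evidence toward the subset, then lowest item index.  Once
no candidate completes any deficient pair the trial stops growing
(minimum size 3).

The two tie-breaks matter more than they look.  Late in a session the
only deficient pairs are tight ones — items nearly coincident in the
latent space.  If the remaining slots were padded with arbitrary
(distant) items, the arena rescale would keep those pairs' on-screen
separations tiny and their evidence would grow by ~10^−4^ per trial:
the protocol would effectively never terminate.  Preferring
low-evidence neighbors, and letting trials shrink to the weak set,
makes consecutive trials zoom into unresolved regions, where the arena
rescale magnifies small distances.  This zooming is exactly the
mechanism that gives the multi-arrangement method resolution below the
single-trial noise floor.

## The inverse-MDS estimator

Each trial observes its within-subset distances only up to a
trial-specific scale.  `estimate_dsm()` alternates two closed-form
steps: align each trial to the current estimate with the
least-squares ratio s~t~ = Σ(d~t~·e)/Σ(d~t~²), then re-estimate every
pair as the evidence-weighted mean of its aligned distances (weight =
squared aligned distance).  Numerical choices:

* the update map is homogeneous of degree 1, so the iterate is
  renormalized to unit RMS each pass (otherwise its global scale
  drifts geometrically and a relative-change stopping rule never
  fires);
* convergence is declared when the relative change of the normalized
  estimate falls below 1e-6; the iteration cap is 1000 because
  convergence is geometric with observed per-iteration factors up to
  ~0.97 on realistic sessions (~400–650 passes in the slowest cases);
  hitting the cap raises a warning and returns the current estimate;
* the final DSM is normalized to unit root-mean-square dissimilarity,
  fixing the arbitrary global scale of arrangement data before each
  participant's [0, 1] max-scaling.

A known limitation: placement noise acts as a *noise floor* on small
distances (|d + ε| is biased upward when d is small), so estimated
spaces compress the dynamic range — tight within-cluster distances
come out systematically inflated relative to the planted truth.  With
5% placement noise this is strong enough that fine (subcluster-level)
silhouette structure visible in the planted spaces can be attenuated
in estimated ones, even when the overall DSV correlation with truth
exceeds 0.99.

## Clustering, silhouette and dispersion

The group space is the elementwise median of scaled DSVs (the median,
not the mean, because dissimilarity data are right-skewed; the mean is
available for comparison).  Complete-linkage agglomeration is
performed by `stats::hclust`; cutting its dendrogram at k gives
nested assignments.  The silhouette of an assignment averages
(b − a)/max(a, b) over items (a: mean within-cluster dissimilarity,
b: smallest mean dissimilarity to another cluster; singletons score
0).  `scan_k()` scans k over a range (default 2–15, the scan range is
not a claim about the data) and reports "upticks" — local maxima with
s(k) > s(k−1) and s(k) ≥ s(k+1) — plus always the global maximum; at
the ends of the range the missing neighbor condition is dropped.

Dispersion uses the cluster *cardinality* (item count) as the
denominator, not the pair count: for a cluster of m items the
statistic is the median of the participant's C(m, 2) within-cluster
dissimilarities divided by m.  Group-level assignments are applied
uniformly to every participant so the statistic compares the same
stimuli across people.

## Embedding validation

Classical (Torgerson) MDS double-centers the squared dissimilarities
and eigendecomposes the Gram matrix.  Variance explained is computed
over positive eigenvalues only — estimated DSMs need not be Euclidean,
and negative eigenvalues carry no representable variance.  Each
dimension's sign is flipped so its correlation with valence is
nonnegative (MDS axes have arbitrary sign; the convention makes
reports reproducible).  Dimensions are then labeled by their partial
correlations with normative valence (controlling arousal) and arousal
(controlling valence), with two-sided p-values on n − 3 degrees of
freedom.

## All-subsets regression and the two nulls

Outcome and predictors are z-scored once (sample mean/SD, n − 1
denominator) before the model loop.  The BIC convention is the
Gaussian concentrated-likelihood form n·ln(RSS/n) + p·ln(n) with p
counting the intercept; any affine-consistent convention ranks models
identically, which is all the selection uses.  Ties are broken toward
the smaller subset, then canonical (size, then lexicographic) order.

Randomization for both nulls defaults to a uniform permutation of the
dispersion vector across participants, which breaks the trait link
while preserving both marginals; a parametric Gaussian resample
(sample mean/SD) is available because either reading of "randomized"
is defensible.  Empirical p-values use the add-one convention
p = (1 + #{null ≤ observed})/(1 + n~iter~) so that p is never 0; the
raw-proportion convention is selectable.  Running both nulls with the
same seed couples their randomization streams, so the min-BIC null is
pointwise at least as extreme as the same-model null and
p~FWER~(all) ≥ p(same) holds replicate by replicate, not just in
expectation.

Two calibration facts worth knowing when reading reports.  For a
*fixed* model, p(same) is uniform under the null (the package's tests
check the rejection rate at the 5% level).  For the *selected* model,
p(same) is anti-conservative by construction: the optimal model is
the best of 31 chance fits, so under a global null its p(same) is
small far more often than its nominal level suggests (roughly the
minimum of about five effectively independent uniform p-values).
That inflation is precisely what p~FWER~(all) corrects, and it is why
the two p-values are always reported side by side.

## Problem sizes used by the tests and acceptance script

Simulation sizes are chosen to make each check informative at desk
scale: full 54-item sessions for recovery (one noiseless, 20 at 5%
noise), 50 replicates of 15-participant cohorts for cluster-count
selection, 500 replicates at 200 Monte Carlo iterations for
calibration, 100 replicates at n = 58 for effect recovery (the cohort
size of interest for the regression stage), and a 30-participant
end-to-end determinism run.  The acceptance script uses the same
designs at moderately reduced replicate counts.

## Known limitations

* The evidence-weighting and iteration scheme of inverse MDS are
  reasonable reconstructions of the method's published logic, not a
  port of any reference implementation.
* Dispersion recovery degrades gracefully but measurably with
  placement noise (noise-floor bias above); analyses of very tight
  clusters should treat estimated dispersions as upper bounds.
* Cluster labels ("erotic", "medical", ...) are analyst-supplied
  descriptions; nothing in the package infers semantics.
* Post-selection p(same) should never be interpreted alone; see the
  calibration note above.
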