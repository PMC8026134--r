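---
title: "Goal-dependent value coding: models, inference and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal-dependent value coding: models, inference and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalrsa)
```

## The scientific problem

How valuable an object is depends on what you are trying to do with it: a
wooden chair is excellent fuel for a signal fire and a poor boat anchor.
`goalrsa` implements a complete analysis chain for studying how such
*goal-dependent value* (here called **usefulness**, to distinguish it from
monetary or hedonic value) is represented in behaviour and in multivoxel fMRI
activity patterns. The paradigm it targets has subjects rate 120 everyday
items for usefulness toward two survival goals ("burning" — starting a signal
fire — and "anchoring" — keeping a boat ashore) and for their **confidence**
in each rating, then make two-alternative choices between items and imagine
using items while scanned, 84 trials per session (60 imagination + 24 choice)
over four sessions at TR = 3.36 s.

The package has two halves:

* **analysis** — a behavioural choice model, representational similarity
  analysis (RSA) with searchlight and region-of-interest (ROI) variants,
  cluster-level sign-flip permutation inference, a participation-vector
  overlap statistic, and cross-goal classifier generalisation;
* **simulation** — a generator (`sim_config()`, `generate_ratings()`,
  `generate_choices()`, `generate_beta_patterns()`, `generate_bold()`) that
  plants known statistical structure so every analysis stage can be validated
  end to end, since no public data set exists for this paradigm.

## The behavioural model

Choices are modelled with a mixed-effects logistic regression. The
probability that subject $k$ chooses the right-hand item is

$$P_k(X) = \frac{1}{1 + e^{-Y_k(X)}},\qquad
Y_k(X) = \beta_0 + b_{0k} + \sum_{j=1}^{8} (\beta_j + b_{jk})\, x_j,
\qquad b_{jk} \sim \mathcal N(0, \sigma_b^2),$$

with eight predictors: the goal in force, the right-minus-left usefulness
difference $\Delta U$ under the **congruent** (current) and **incongruent**
(other) goal, the analogous confidence differences $\Delta C$, the two
$\Delta U \!\times\! \Delta C$ interactions, and the monetary-value
difference. `fit_choice_model()` offers three estimators:

* `"summary"` (default): per-subject maximum-likelihood logistic fits
  followed by one-sample $t$ tests on the subject coefficients. It is
  deterministic and convergence-robust, but per-subject ML estimates carry
  the usual upward small-sample bias (with ~96 choice trials and 9
  parameters per subject), so its group means overestimate large
  coefficients; use it when only signs/tests are needed.
* `"firth"`: the same summary-statistics scheme with per-subject
  *bias-reduced* fits (`firth_logistic()`, Firth's adjusted score). This
  removes the $O(1/n)$ bias and makes separation impossible, and in
  simulation its group-mean 95% CIs cover the planted coefficients at the
  nominal rate (0.94–0.95 over 100 replicates at 30 subjects). Preferred
  when the coefficient *values* matter.
* `"mixed"`: a random-slopes model via `lme4::glmer` with a random
  intercept and uncorrelated random slopes on the two congruent predictors.
  Because random slopes on the remaining predictors are not modelled (all
  nine at once need minutes per fit and routinely fail to converge), the
  fixed effects are mildly attenuated relative to the subject-conditional
  coefficients, which costs a few points of CI coverage.

**Units.** The sliders are unnumbered, so the numeric scale is arbitrary; we
store ratings on 0–100. The choice-model predictors are rescaled to the unit
interval (`scale_predictors = TRUE`), because logistic coefficients published
for this model (e.g. $\beta \approx 4.7$ for congruent $\Delta U$) are only
numerically meaningful when the rating range is ~1: on a raw 0–100 scale the
same behaviour corresponds to $\beta \approx 0.047$ and the logistic would
saturate long before 4.7. The per-subject consistency threshold (exclusion of
subjects with a congruent-usefulness slope below 0.025) is defined per *raw
slider unit*, so `exclude_inconsistent()` takes the slider width and converts.
The quadratic confidence coefficient (0.03) is in raw slider units
(confidence units per squared usefulness unit) and is fitted on raw units.

`fit_confidence_quadratic()` regresses confidence on centred usefulness and
its square, one fit per subject and goal (intercept and linear terms are
goal-specific; the quadratic coefficient is invariant to the centring shift),
then averages the quadratic coefficients within subject and tests them across
subjects.

## Representational similarity analysis

Condition patterns are one multivoxel beta map per (item, goal) condition —
240 in the full design — estimated by a least-squares-all GLM
(`fit_condition_betas()`): one HRF-convolved regressor per condition, plus
per-session choice indicator, motion, discrete-cosine drift (cutoff 128 s)
and intercept nuisances. LSA is exact here because every condition occurs
once. The canonical HRF is the conventional double-gamma (peak ~5 s,
undershoot ~15 s, 1:6 amplitude ratio, 32 s support, unit peak).

Brain dissimilarity is $d = 1 - r$ (Pearson) between condition patterns
(`brain_rdm()`). Model RDMs are:

* `model_identity()` — $d_{ij} = 1 - \delta_{ij}$ on **items** (same item
  under different goals counts as identical);
* `model_value()` — $d_{ij} = |V_i - V_j|$ for any per-condition scalar
  (congruent usefulness, confidence, monetary value);
* `model_material()` — Euclidean distance between 4-component material
  compositions (wood, metal, plastic, fabric), with the same-item cross-goal
  cells masked out. That masking matters: on the retained cells the identity
  model is constant, so the two models are exactly orthogonalised.

Model and brain RDMs are compared by Spearman rank correlation over the
strict lower triangle restricted to the intersection of their cell masks
(`compare_rdms()`). Before ROI comparisons, patterns are spatially
prewhitened (`prewhiten()`): multiplied by $\Sigma^{-1/2}$ where $\Sigma$ is
the residual voxel covariance shrunk toward its diagonal with the analytic
(Schäfer–Strimmer-type) intensity. Shrinkage deliberately under-whitens
near-singular directions — stability is preferred over exact whitening.

The searchlight (`searchlight_map()`) scans a 9-mm (3-voxel) sphere across
the mask, computes the local brain RDM and its Spearman correlation with the
model, and assigns the value to the centre voxel; centres whose sphere
retains fewer than `min_voxels = 10` in-mask voxels are invalid (no padding —
this avoids border bias). Maps are smoothed with a mask-normalised separable
Gaussian (`smooth_map()`, FWHM 8 mm by convention).

A caution specific to rank-based RSA: correlating two *metric* structures
gives a small positive bias even for pure-noise patterns (we measure a mean
searchlight $\rho \approx 0.03$ under the null). Group inference is
therefore always against a permutation or sign-flip null, never against
"$\rho = 0$" parametrically.

## Group inference

`cluster_permutation_test()` implements the nonparametric cluster-level test:
a one-sample $t$ across subjects at each voxel, a one-sided cluster-defining
threshold at $p < 0.001$, clusters by 6-connectivity, and a family-wise-error
$p$ for each observed cluster against the null distribution of the *maximum*
cluster size under random sign flips of whole subject maps (default 5,000
flips; exact enumeration when $2^{n} \le n_\text{perm}$). The estimator bound
$p \ge 1/(n_\text{perm}+1)$ holds by construction, and the false-positive
rate is verified at the nominal 5% over 200 pure-noise group simulations in
the acceptance suite. Subject maps enter as raw $\rho$; a Fisher-$z$
transform changes nothing under sign flipping (it is monotone and odd), so
none is applied by default.

ROI analyses (`roi_rsa_group()`) use 10-mm spheres; group significance is a
one-sided Wilcoxon signed-rank test of the subject $\rho$ values against
zero, which drops the normality assumption correlation coefficients tend to
violate.

## The participation-vector overlap statistic

To ask whether usefulness and confidence are encoded by the *same* voxel
population within an ROI, `participation_vectors()` regresses each voxel's
trial-by-trial activity separately on usefulness and on confidence and takes
the absolute slopes $B_U, B_C$ (two simple regressions by default — the
bivariate variant is a flag). `overlap_test()` computes each subject's
Spearman correlation $\rho(B_U, B_C)$, summarises the group with a Wilcoxon
signed-rank $z$, and calibrates it by permutation.

Two permutation schemes exist because the source descriptions of this method
disagree: permuting the **trial labels** of the confidence predictor before
recomputing $B_C$ (the default), or permuting the **voxel labels** of $B_C$
(`scheme = "voxel"`). They answer subtly different questions. The trial
scheme preserves each voxel's overall responsiveness in the null: a voxel
with a large activity range keeps a large |slope| under permutation, so this
null is conservative when strong codes make responsiveness itself
informative. The voxel scheme destroys all voxel-level structure and is the
more liberal null. Both are provided; neither is asserted to be "the"
correct one.

Note on calibration: the null of this two-sided test is *independent*
usefulness/confidence tuning across voxels. Fully *disjoint* populations are
not a null — they make $B_U$ and $B_C$ systematically anti-correlated, and
detecting that segregation (negative $z$) is precisely what the test is
for. Under independent tuning both schemes hold the nominal level in
simulation; under strongly segregated populations the voxel scheme detects
the negative overlap while the trial scheme, at high SNR, may not (its null
keeps each voxel's responsiveness, which tracks the segregation itself).

## Cross-goal generalisation (common currency)

`xclass_subject()` tests whether the usefulness code transfers across goals.
Per goal, items are split into the highest and lowest usefulness quartile
(subject-level split, `split_high_low()`; ties at a boundary are resolved by
stable item order so groups stay equal). A linear SVM (cost 1, features
standardised on the training data only) is scored within-goal by stratified
10-fold cross-validation and *across* goals by applying the frozen model —
including its frozen standardisation — to all retained items of the other
goal (no folding is needed: nothing leaks across goals). Group statistics are
one-sided Wilcoxon tests against chance and a paired within-vs-cross test.

A *goal-general* planted code (one linear map of congruent usefulness shared
by both goals) yields cross-goal accuracy statistically indistinguishable
from within-goal accuracy; a *goal-specific* code (two independent maps)
yields chance-level transfer with intact within-goal accuracy — the
qualitative dissociation between a common-currency region and a
goal-specific one. The quartile split is per subject per goal by default
(`pooled_split = TRUE` labels each goal's items against cutoffs pooled over
both goals).

## What the generator plants, and what it does not

`generate_ratings()` draws the two goals' usefulness and the monetary value
from a trivariate Gaussian copula whose latent correlations are inverted
analytically ($\rho_{\text{latent}} = 2\sin(\pi r/6)$) so the uniform
margins hit the target Pearson correlations exactly: cross-goal $r = 0.12$,
monetary vs burning $-0.06$, monetary vs anchoring $0.17$ — the weak-sharing
regime this paradigm requires. Confidence is a quadratic function of
usefulness centred on the scale midpoint (coefficient 0.03, baseline 12% of
the scale, linear term 0.05, Gaussian noise SD 3); midpoint centring keeps
the curve inside the slider bounds, where sample-mean centring occasionally
clipped the top of the parabola and visibly biased the recovered
coefficient. Material compositions are item-level Dirichlet(1,1,1,1) draws —
exactly on the simplex.

`generate_choices()` lays out sessions with alternating goals, draws choice
pairs from the 10 most recent imagination trials, and samples choices from
the logistic model above with planted group coefficients (4.71 congruent
$\Delta U$, −0.11 incongruent $\Delta U$, −0.64 congruent $\Delta C$, zero
elsewhere) and independent subject random slopes (SD 0.5; the monetary
slope's spread is scaled by the price range so raw currency units cannot
dominate the linear predictor).

`generate_beta_patterns()` builds each condition pattern as a weighted sum
of planted codes over spatially compact regions — item identity, material
composition, goal-general usefulness, goal-specific usefulness, confidence —
plus i.i.d. Gaussian voxel noise, with matching pure-noise residual samples
attached for prewhitening. `shared_population_fraction` controls how many
usefulness-carrying voxels reuse their exact weights for confidence
(fraction 1 ⇒ the participation vectors coincide; fraction 0 ⇒ independent
populations). `generate_bold()` convolves the event amplitudes with the
canonical HRF on a microtime grid and adds slow cosine drift, a small
motion-coupled component (bounded random-walk covariates) and white noise.

**Chosen constants** (nothing in the paradigm fixes them; each was set once
and documented here):

* `noise_sd_pattern = 2` with unit code weights and 137-voxel regions (a
  10-mm sphere at 3-mm voxels). This puts within-goal decoding accuracy near
  90% and keeps the goal-specific cross-goal accuracy within ±2.5 points of
  chance at $n = 30$ — codes strong enough that every mechanism is testable
  at desk scale. Real cortical SNR is far lower (published accuracies for
  this paradigm are 52–54%), so synthetic results validate the *machinery
  and the qualitative dissociations*, not effect sizes.
* The searchlight localisation scenario plants its cube code with weight 2.5:
  at weight 1 the local RDM correlation contrast is real but small (~0.09),
  and the scenario exists to verify spatial localisation, not power.
* Slider 0–100, price range 1–200 currency units, lognormal reaction times
  around 1.4 s.
* Grid default 20×20×20 voxels at 3 mm — desk-scale searchlight and
  cluster-permutation runs; larger grids are configuration, not code.

**Not emulated**: anatomical geometry, physiological noise spectra, scanner
drift beyond smooth cosines, spatial autocorrelation of noise, motion
artefacts beyond linear coupling, and any preprocessing (the synthetic data
are born on a common grid). Passing tests therefore say nothing about
registration or artefact robustness on real data.

## Numerical choices and degenerate inputs

* Quartile split: bottom/top $\lfloor n/4 \rfloor$ items after a stable
  (value, item-id) sort — equal groups under any tie pattern; all-constant
  values are an error.
* `brain_rdm()` flags conditions with zero pattern variance in the cell mask
  rather than producing NaNs; `compare_rdms()` requires ≥3 unmasked cells.
* Separation in per-subject logistic fits is detected (non-convergence, |β|
  > 50, or all fitted probabilities pinned) and those subjects are excluded
  from group tests with a warning.
* `prewhiten()` floors eigenvalues at `1e-10` of the largest; it refuses to
  run on fewer than 2 residual samples.
* Cluster $p$ uses the $+1$-corrected estimator for random flips and the
  exact fraction under full enumeration.
* The sign-flip $t$ exploits the flip-invariance of $\sum_i x_i^2$, so the
  whole permutation distribution is two matrix products.

## Problem sizes used in the shipped test and acceptance runs

Unit tests run on reduced designs (24 items, 2 sessions, 10³ grids).
Recovery suites use the full paradigm scale — 30 subjects × 120 items, 96
choice trials per subject — with 100 replicates per planted parameter.
Cluster-permutation calibration uses 200 pure-noise group studies of 12
subjects on a 20³ grid with 250 sign flips each; noise maps are smoothed
(FWHM 8 mm) before the group test, matching the analysis chain — on
unsmoothed white noise the CDT-0.001 clusters are nearly all singletons and
the discreteness of the max-cluster-size null makes the test conservative
(false-positive rate ≈ 0.01) rather than nominal. The structure-discrimination
runs use 30 subjects per scenario. The acceptance script repeats the
headline computations at these sizes with a caller-supplied seed.

The mixed-effects choice estimator reports Wald intervals on a $t$
reference with $n_{\text{subjects}}-1$ degrees of freedom rather than the
asymptotic normal: subjects, not trials, are the effective replication unit
for slopes carrying random effects, and at 30 subjects normal-based
intervals measurably under-cover the planted coefficients.

## Known limitations

* The LSA condition-beta GLM assumes each condition occurs exactly once; a
  least-squares-separate estimator for repeated conditions is out of scope.
* No crossvalidated (crossnobis) distances — the correlation distance is the
  method under study.
* BOLD simulation and GLM share the same HRF and microtime discretisation,
  so beta recovery does not probe HRF misspecification.
* The trial-permutation null of `overlap_test()` retains responsiveness
  structure (see above); at very high SNR it is conservative by design.
* No TFCE, no variance smoothing, no AR(1) prewhitening of time series, no
  anatomical normalisation — all out of scope for this analysis chain.
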