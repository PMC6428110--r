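---
title: "Methods: age trajectories of biomarker co-dependency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age trajectories of biomarker co-dependency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the model

Clinical biomarkers are strongly co-dependent — glycohemoglobin tracks
glucose, height tracks blood pressure — and in a cross-sectional survey
those co-dependencies need not be the same at age 25 as at age 75. This
package quantifies how the *pairwise correlation structure* of a
biomarker panel changes across age in a weighted cross-sectional cohort,
and whether that structure differs between demographic strata.

The unit of analysis is the per-age survey-weighted Pearson correlation.
For a biomarker pair $(u, v)$ and integer age $a$, participants of age
$a$ give

$$ r_{uv}(a) \;=\; \frac{\sum_i \tilde w_i (x_{iu}-\bar x_u)(x_{iv}-\bar x_v)}
{\sqrt{\sum_i \tilde w_i (x_{iu}-\bar x_u)^2 \sum_i \tilde w_i (x_{iv}-\bar x_v)^2}},
\qquad \tilde w_i = w_i / \textstyle\sum_j w_j, $$

with a bootstrap standard error from resampling rows within the age bin
(each row keeps its survey weight; weights renormalize within the
resample). Each pair's series $\{r_{uv}(a), \mathrm{se}_{uv}(a)\}$ is
then *meta-regressed* on age — weighted least squares with weights
$1/\mathrm{se}^2$ — and the slope tested against zero. P-values are
Bonferroni-corrected by the family size (the number of pairs), stored
unclamped so corrected values above 1 are legal, and displayed as
negative logs capped at 308 (the negative log of the smallest
representable double).

Significant trends are classified into six classes by the slope sign and
the signs of the fitted line at the youngest and oldest ages: decreasing
and remaining positive (`dec_pp`), decreasing across zero (`dec_pn`),
decreasing and remaining negative (`dec_nn`), and the three increasing
mirrors (`inc_nn`, `inc_np`, `inc_pp`). An endpoint that is exactly zero
inherits the other endpoint's sign, so ties break toward the
non-switching class; a slope of exactly zero is never classified.

Three further layers reuse the same meta-regression machinery:

* **Mean absolute correlation.** Per age, the mean and SD of $|r|$
  across all pairs; the mean is regressed on age with
  $\mathrm{se} = \mathrm{SD}/\sqrt{\#\text{pairs}}$.
* **Predictability.** Per age window, each biomarker is predicted from
  all the others by an elastic net (mixing 0.5), and the uncorrected
  out-of-sample $R^2$ from a 50/50 cross-fit (fit on one half, predict
  the other, swap, score all held-out predictions together) is the
  response. Negative $R^2$ — the model predicting worse than the held-out
  mean — is reported as-is.
* **Coefficients.** The elastic net refit on the full window (no split)
  at its CV-selected penalty gives per-predictor coefficients, with
  uncertainty from a parametric bootstrap (Gaussian noise at the
  residual SD, refit at the *same* penalty).

Demographic contrasts compare two strata either at **baseline** (the
full-age-range quantity per group, $z = (\hat\theta_a - \hat\theta_b) /
\sqrt{\mathrm{sd}_a^2 + \mathrm{sd}_b^2}$, normal reference) or as
**trajectories** (the per-age difference, with variance the sum of the
two bootstrap variances, meta-regressed on age). The negative control is
a *random split* of the same cohort into two halves, pushed through the
identical pipeline: any findings there are spurious by construction.

# Preprocessing

A raw cohort table (participants × age, survey weight, sex, ethnicity,
biomarkers) is reduced to a complete analysis matrix in four steps:

1. **Completeness extraction.** Iteratively remove whichever entity has
   the highest missing fraction — the worst row or the worst biomarker
   column — until no missing cells remain. At a tie the row goes first;
   this keeps more biomarkers, which is the point of the panel. All
   removals are logged.
2. **Redundancy filter.** Greedy scan of pairs in input column order:
   when $|r| > 0.9$ (survey-weighted, full cohort) the *later* column is
   dropped. Input-order determinism is a deliberate, reproducible stand-in
   for a curator's choice of which duplicate to keep.
3. **Gaussianizing transforms.** Per biomarker, the transform among
   {identity, log, exp} minimizing the absolute weighted skewness is
   applied. The log shifts non-positive columns by
   $\min + 10^{-6}(\max-\min)$ (recorded); the exp is applied after
   centering, which leaves skewness unchanged but prevents overflow, and
   a transform that still overflows simply loses the competition.
   Identity is included so already-Gaussian variables are untouched.
4. **Weighted standardization.** Weighted mean 0, weighted variance 1,
   with normalized weights; the recorded moments replay the
   standardization bit for bit. These moments are invariant to
   duplicating a row while halving its weight, and to any positive
   rescaling of the weights.

Repeated-measure averaging (e.g. several blood-pressure readings) is a
generic pre-step: a map `{output: [inputs]}` averaged row-wise.

# Numerical and inferential choices

**Dispersion-scaled meta-regression.** The per-bin standard errors are
bootstrap estimates: noisy at finite $B$ and slightly downward-biased in
finite bins. Treating them as exact (pure fixed-effect weighted least
squares with a normal reference) proved anti-conservative in calibration
runs: the null distribution of the slope statistic had standard
deviation 1.04–1.09 instead of 1, which at Bonferroni-depth tails turns
a nominal 5% family-wise rate into 9–13%. `meta_regress()` therefore
inflates the slope SE by the estimated residual dispersion
$\max(1, Q/\mathrm{df})$ — exactly the scale a weighted `lm()` would
estimate — and refers the slope to a $t$ distribution on
$\#\text{bins} - 2$ degrees of freedom. The floor at 1 means exact
series, degenerate cases and under-dispersed data reproduce fixed-effect
behaviour unchanged; over-dispersion (imperfect SEs) widens inference.
After this change, 2 of 100 null cohorts showed any significant
trajectory in a 28-pair panel at Bonferroni 0.05.

A residual caveat remains: because the sampling variance of a
correlation depends on the correlation itself
($\mathrm{se} \propto 1 - r^2$), the inverse-variance weights are
correlated with the estimate errors, which steepens any true trend by
roughly 0.3 SE. Two-SE intervals therefore cover the planted slope at
about 93–94% rather than the nominal 95%. This is inherent to
inverse-variance weighting of raw correlations (a variance-stabilizing
transform would remove it, but would change the estimand away from
correlation units).

**Other choices.**

* Bins with fewer than `min_n = 100` participants are dropped from a
  series (never imputed), with a warning.
* Constant inputs raise errors rather than returning NaN correlations.
* The planted correlation matrix of the generator is clipped to
  $[-0.95, 0.95]$ and projected to the nearest positive-semidefinite
  correlation matrix (Higham's alternating projections) per integer age;
  an already-valid matrix passes through bit-identical.
* The elastic-net penalty is chosen at the CV minimum (not the 1-SE
  rule) over a 100-point geometric path down to $10^{-4}$ of the
  data-driven maximum — the minimal reading of "optimal lambda".
* The elastic-net loss is unweighted on the already weight-standardized
  matrix by default; `predict_config(weighted_loss = TRUE)` switches to
  survey-weighted loss.
* Age windows for predictability are the non-overlapping tiling of the
  age range, equalized to a common quota by seeded subsampling; within a
  trajectory family all windows use identical n, because window size
  affects model quality and unequal sizes would masquerade as an age
  trend.
* The parametric-bootstrap penalty is selected once per window per
  target and held fixed across refits, isolating coefficient (not
  tuning) variability.
* Coefficient p-values use the normal approximation on the parametric
  bootstrap SD.
* Control groups are drawn once per seed and reused across analyses.
* BP/AU support: cluster identity across bootstrap trees is exact
  member-set equality; bootstrap probabilities of 0 or 1 are clamped by
  $1/(2B)$ before the multiscale fit; a cluster at the boundary on
  *every* scale carries no curvature information and is assigned support
  100 (or 0) directly. The multiscale model is
  $z(\rho) = v\sqrt\rho + c/\sqrt\rho$ fit by weighted least squares over
  $\rho \in \{0.5, \dots, 1.4\}$, with $AU = 100\,(1 - \Phi(v - c))$;
  the signs are fixed by requiring $AU = BP$ when the curvature $c$ is
  zero. Support runs with $B < 100$ are refused unless explicitly
  allowed.
* Clustering height is one minus the mean between-cluster correlation,
  which *is* average linkage on $D = 1 - r$; the implementation uses
  `stats::hclust(method = "average")` and is tested against a naive
  $O(n^3)$ re-implementation.
* One global seed expands into per-stage child seeds through a fixed
  affine congruential map keyed by a stage label, so adding a stage
  never perturbs another stage's draws and every result is reproducible
  byte for byte.

# The synthetic cohort generator

The generator emulates the statistical structure the pipeline consumes,
with known ground truth: ages uniform on the integers of $[20, 80)$;
biomarkers multivariate Gaussian per integer age with correlation
$R(a) = \mathrm{clip}(A + B(a-20))$ projected to the nearest valid
correlation matrix; lognormal(0, 0.5) survey weights (heavy-tailed
positive, like national-survey analysis weights); optional per-stratum
shifts of intercept and slope on planted pairs; completely-at-random
missingness; optional near-duplicate columns.

What it does *not* emulate, and what passing tests therefore do not
show about real data: marginal age trends in biomarker means (the
synthetic age-association table is null by design), non-Gaussian
marginals (except where tests construct them explicitly), survey design
effects beyond a scalar weight (no strata or PSUs), non-linear
correlation trajectories, and missingness that is informative rather
than MCAR. The defaults mirror the cohort scale the method is built for
(27,508 participants, 50 biomarkers, ages 20–79); analyses and tests
state smaller panels explicitly where they use them.

# Problem sizes used in the shipped analyses and tests

The `analysis/` drivers run a 27,508-participant, 20-biomarker cohort
with $B = 200$ bootstrap replicates, 5-year prediction windows at the
automatic (smallest-window) quota, and $B = 100$ parametric refits —
sizes at which every planted effect is comfortably detectable. The test
suite validates calibration at the same per-bin density (about 460
participants per integer age) with two- to ten-biomarker panels, 200
replicate cohorts for the coverage and family-wise-error properties, and
$B = 200$; the negative-control acceptance run uses the full 50-biomarker
panel (1,225 pairs) at $n = 20{,}000$ and $B = 200$.

# Interfaces

The package functions are the interface; the numbered scripts under
`analysis/` are thin narrative drivers over them, and
`scripts/acceptance.R` recomputes the negative-control calibration from
scratch. No separate shell tool is provided: an analysis of this kind is
driven from R, and each driver is a worked example of the corresponding
module.

# Known limitations

* Cross-sectional trajectories confound aging with generational effects;
  nothing here distinguishes them.
* The linear trajectory model is deliberately minimal; genuinely
  non-linear trends are only detected insofar as they have a linear
  component.
* With few age windows the $t$ reference makes deep Bonferroni
  significance unreachable (by design: four windows give two residual
  degrees of freedom); trajectory families need on the order of ten or
  more bins to have power.
* Post-selection inference for elastic-net coefficients is not
  corrected; the parametric bootstrap quantifies stability at a fixed
  penalty, and power for coefficient trajectories is accordingly low.
* The 2-SE coverage of planted slopes tops out near 93–94% (see the
  dispersion discussion above).
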