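# agecodep — age trajectories of biomarker co-dependency structure

Clinical biomarkers (cholesterol, glucose, blood pressure, anthropometry)
are strongly co-dependent, and in a cross-sectional cohort those
co-dependencies themselves drift with age: a pair of biomarkers can be
positively correlated at 25 and negatively correlated at 75. `agecodep`
is an R package plus a numbered analysis workflow for quantifying that
drift in a survey-weighted cohort, for epidemiologists and aging
researchers working with panels of ~50 biomarkers in national-survey-style
data (tens of thousands of participants with analysis weights).

## What it computes

For each biomarker pair (u, v) and integer age a, the survey-weighted
Pearson correlation

    r_uv(a) = Σ w̃ᵢ (x_iu − x̄_u)(x_iv − x̄_v) / √(Σ w̃ᵢ (x_iu − x̄_u)² · Σ w̃ᵢ (x_iv − x̄_v)²)

with a within-bin bootstrap SE. Each series r_uv(·) is meta-regressed on
age (weights 1/se², dispersion-scaled, t reference), Bonferroni-corrected
over the 1,225-pair family, and every significant trend is classified
into six classes by slope sign and the signs of the fitted endpoints:
decreasing and staying positive / crossing zero / staying negative, and
the three increasing mirrors. On top of this sit:

* the trend of the **mean |r|** across the panel;
* **cluster support**: weighted average-linkage clustering on 1 − r with
  bootstrap probability (BP) and multiscale-bootstrap approximately
  unbiased (AU) values, significant at AU > 95;
* **predictability**: cross-fitted elastic-net R² (uncorrected, possibly
  negative) of each biomarker from all others, per equalized age window;
* **coefficient trajectories**: the elastic-net coefficients refit per
  window with parametric-bootstrap uncertainty;
* **demographic contrasts**: baseline and trajectory differences between
  sexes/ethnicities, calibrated against a random split of the same
  cohort (the negative control, which must find nothing).

A synthetic cohort generator plants known age-varying correlation
structure (Gaussian copula, linear-in-age correlations, nearest-PSD
projection per age, lognormal survey weights, demographic modifiers,
missingness, near-duplicate columns), so the entire pipeline is
validated against ground truth.

## Worked example

Plant a sign-switching correlation (+0.40 at age 20 falling to −0.30 at
age 79) between the first two of five biomarkers, and recover it:

```r
library(agecodep)

plan <- data.frame(i = 1, j = 2, intercept = 0.4, slope = -0.7 / 59)
cfg <- synth_config(n_participants = 24000, n_biomarkers = 5,
                    correlation_plan = plan, seed = 7)
cohort <- generate_cohort(cfg)

pp <- preprocess(cohort)              # complete, transform, standardize
ct <- corr_trajectories(pp$table, B = 200, seed = 1)
ct$fits[1:3, c("pair", "slope", "slope_se", "start_value", "end_value",
               "neg_log_corrected_p", "class")]
```

```
       pair     slope slope_se start_value end_value neg_log_corrected_p  class
1 bm01~bm02 -0.012383 0.000367    0.421405 -0.309188              38.062 dec_pn
2 bm01~bm03  0.000273 0.000421   -0.016253 -0.000175              -0.716   none
3 bm01~bm04 -0.000386 0.000436   -0.000678 -0.023467              -0.579   none
```

The planted pair is recovered with the right slope (−0.0119 planted),
fitted endpoints near +0.4/−0.3, and class `dec_pn` (decreasing,
positive → negative). Unplanted pairs have corrected p-values above 1 —
hence *negative* `neg_log_corrected_p`, which is deliberate: corrected
p-values are stored unclamped, and underflowing ones display as the
sentinel 308. The panel-wide mean |r| trend is flat, as planted:

```r
mean_abs_corr_trend(ct$panel)$fit
#> mean |r| slope: -1.42e-04 per year (p = 0.37)
```

## The analysis workflow

The numbered drivers under `analysis/` run the full study on a
27,508-participant synthetic cohort with 20 biomarkers and every planted
feature the pipeline must detect (all six trajectory classes, a tight
cluster, sex-specific baseline and trajectory effects, a near-duplicate
column, 1% missingness):

```sh
Rscript analysis/01_simulate.R        # cohort -> scratch/cohort.csv
Rscript analysis/02_preprocess.R      # analysis matrix + drop/transform report
Rscript analysis/03_correlation_trajectories.R
Rscript analysis/04_clustering.R      # BP/AU support, Newick export
Rscript analysis/05_predictability.R  # elastic-net R² per 5-year window
Rscript analysis/06_coefficients.R    # coefficient trajectories
Rscript analysis/07_group_differences.R  # sex contrast + random-split controls
```

Each writes small summary tables under `results/`. In the shipped run,
every planted trajectory is recovered in its correct class, the planted
3-biomarker cluster gets BP = AU = 100, the two planted sex differences
are the only significant contrasts, and the random-split controls find
exactly zero — the calibration the whole design rests on.

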