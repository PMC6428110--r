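#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# A synthetic cross-sectional cohort shaped like a national health survey
# extract: 27,508 participants aged 20-79 with lognormal survey weights,
# sex and ethnicity labels, and 20 biomarkers whose pairwise correlations
# drift linearly with age. The plant covers every trajectory class the
# pipeline is meant to detect, a tight 3-biomarker cluster, a baseline
# and a trajectory sex difference, plus a near-duplicate column and 1%
# missingness to exercise preprocessing. Ground truth is known exactly,
# so every downstream stage can be judged against it.

suppressPackageStartupMessages(library(agecodep))
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

seed <- 1

plan <- data.frame(
  i = c(1, 3, 5, 7, 9, 11, 11, 12, 14, 16, 18),
  j = c(2, 4, 6, 8, 10, 12, 13, 13, 15, 17, 19),
  intercept = c(0.40, 0.55, -0.10, -0.30, 0.15, 0.75, 0.75, 0.75,
                0.30, 0.04, 0.35),
  slope = c(-0.7, -0.3, -0.25, 0.55, 0.25, 0, 0, 0, 0, 0, 0) / 59
)
# sex-specific structure: females get a strong bm16~bm17 baseline
# correlation and a declining bm18~bm19 trajectory; males stay flat
group_plan <- data.frame(
  variable = "sex", level = "female",
  i = c(16, 18), j = c(17, 19),
  d_intercept = c(0.28, 0.00),
  d_slope = c(0, -0.35 / 59)
)

cfg <- synth_config(
  n_participants = 27508,
  n_biomarkers = 20,
  correlation_plan = plan,
  background_correlation = 0.05,
  group_plan = group_plan,
  missing_rate = 0.01,
  duplicate_spec = data.frame(source = "bm20", r = 0.95),
  seed = seed
)

message("generating cohort ...")
cohort <- generate_cohort(cfg)
message(sprintf("cohort: %d participants, %d biomarker columns, %.1f%% cells missing",
                nrow(cohort), length(biomarker_names(cohort)),
                100 * mean(is.na(as.matrix(cohort[, biomarker_names(cohort)])))))

utils::write.csv(cohort, "scratch/cohort.csv", row.names = FALSE, na = "")
saveRDS(list(cfg = cfg, plan = plan, group_plan = group_plan),
        "scratch/truth.rds")
write_run_manifest("results/run_manifest.json", seed = seed,
                   n_participants = cfg$n_participants,
                   n_biomarkers = cfg$n_biomarkers)
message("wrote scratch/cohort.csv and results/run_manifest.json")
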