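#!/usr/bin/env Rscript
# Stage 5 — cross-fitted elastic-net predictability per age window.
#
# The age range is tiled with 5-year windows equalized to 1,800
# participants each (comparing model performance across windows of
# unequal size would bias the trajectories). Each biomarker is predicted
# from all the others by a 50/50 cross-fit elastic net (alpha = 0.5,
# 100-value penalty path, 10-fold CV); the uncorrected out-of-sample R^2
# per window is meta-regressed on the window midpoint.

suppressPackageStartupMessages(library(agecodep))

tb <- utils::read.csv("scratch/matrix.csv", stringsAsFactors = FALSE)
bms <- biomarker_names(tb)

wins <- equalize_windows(tb, window_years = 5,
                         samples_per_window = "auto", seed = 31)
message("windows: ", paste(names(wins), collapse = " "),
        " windows")

cfg <- predict_config(boot_B = 200)
records <- predictability_records(wins, cfg, seed = 32)

traj <- do.call(rbind, lapply(bms, function(tg) {
  out <- predictability_trajectory(records[records$target == tg, ],
                                   family_size = length(bms))
  cbind(data.frame(target = tg), out)
}))
message(sprintf("%d of %d predictabilities change significantly with age",
                sum(traj$class != "none"), nrow(traj)))
print(traj[traj$class != "none",
           c("target", "slope", "start_value", "end_value", "class")],
      digits = 3)

base <- records[records$window == names(wins)[1], ]
message(sprintf("window-1 R^2: mean %.3f, min %.3f, max %.3f",
                mean(base$r2), min(base$r2), max(base$r2)))

trend <- mean_predictability_trend(records)
message(sprintf("mean predictability slope: %.2e /yr (p = %.3g)",
                trend$fit$slope, trend$fit$p))

utils::write.csv(records, "results/predictability_records.csv",
                 row.names = FALSE)
utils::write.csv(traj, "results/predictability_trajectories.csv",
                 row.names = FALSE)
message("wrote results/predictability_records.csv and trajectories")
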