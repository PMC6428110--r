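#!/usr/bin/env Rscript
# Stage 6 — elastic-net coefficient trajectories.
#
# For each target, the elastic net is refit on each full window (no
# train/test split) at its CV-selected penalty; coefficient uncertainty
# comes from a 100-fold parametric bootstrap at that fixed penalty, and
# each (target, predictor) coefficient series is meta-regressed on the
# window midpoint with the six-class taxonomy, Bonferroni over all
# ordered pairs.

suppressPackageStartupMessages(library(agecodep))

tb <- utils::read.csv("scratch/matrix.csv", stringsAsFactors = FALSE)
bms <- biomarker_names(tb)
family <- length(bms) * (length(bms) - 1)

wins <- equalize_windows(tb, window_years = 5,
                         samples_per_window = "auto", seed = 31)
# the sign-switching planted pair (bm01, bm02) plus a flat control target
targets <- c("bm01", "bm02", "bm14")
rec <- coefficient_records(wins, predict_config(boot_B = 200), B = 100,
                           seed = 41, targets = targets)

traj <- do.call(rbind, lapply(targets, function(tg) {
  preds <- unique(rec$predictor[rec$target == tg])
  do.call(rbind, lapply(preds, function(pr) {
    rows <- rec[rec$target == tg & rec$predictor == pr, ]
    out <- coefficient_trajectory(rows, family_size = family)
    cbind(data.frame(target = tg, predictor = pr), out)
  }))
}))
message(sprintf("%d of %d coefficient series tested change significantly",
                sum(traj$class != "none"), nrow(traj)))
print(traj[traj$class != "none",
           c("target", "predictor", "slope", "start_value", "end_value",
             "class")], digits = 3)

# heatmap-ready wide matrix of full-cohort coefficients
full <- tb
attr(full, "window") <- "all"
attr(full, "mid") <- mean(full$age)
wide <- do.call(rbind, lapply(bms, function(tg) {
  f <- fit_full_coefficients(full, tg, predict_config(), seed = 42)
  stats::setNames(c(f$records$coefficient), f$records$predictor)[bms[bms != tg]]
}))
rownames(wide) <- bms
utils::write.csv(round(wide, 4), "results/coefficients_full_cohort.csv")
utils::write.csv(rec, "results/coefficient_records.csv", row.names = FALSE)
utils::write.csv(traj, "results/coefficient_trajectories.csv",
                 row.names = FALSE)
message("wrote results/coefficient_*.csv")
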