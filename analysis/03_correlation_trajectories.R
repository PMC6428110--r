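#!/usr/bin/env Rscript
# Stage 3 — age trajectories of the pairwise correlations.
#
# Per integer age, every pairwise survey-weighted correlation with a
# B = 200 bootstrap SE; each of the 171 series is meta-regressed on age
# and classified into the six-class taxonomy at Bonferroni 0.05; then
# the trend in the mean absolute correlation.

suppressPackageStartupMessages(library(agecodep))

tb <- utils::read.csv("scratch/matrix.csv", stringsAsFactors = FALSE)
truth <- readRDS("scratch/truth.rds")

ct <- corr_trajectories(tb, B = 200, seed = 11, min_n = 100)
fits <- ct$fits
message(sprintf("%d of %d correlations change significantly with age",
                sum(fits$class != "none"), nrow(fits)))
print(trajectory_summary_table(fits$class, family_size = nrow(fits)))

planted <- sprintf("bm%02d~bm%02d", truth$plan$i, truth$plan$j)
show <- fits[fits$pair %in% planted,
             c("pair", "slope", "slope_se", "start_value", "end_value",
               "neg_log_corrected_p", "class")]
message("planted pairs as recovered:")
print(show, digits = 3)

trend_all <- mean_abs_corr_trend(ct$panel)
trend_sig <- mean_abs_corr_trend(ct$panel, fits = fits,
                                 restrict_to_significant = TRUE)
message(sprintf("mean |r| slope, all pairs: %.2e /yr (p = %.2e)",
                trend_all$fit$slope, trend_all$fit$p))
message(sprintf("mean |r| slope, significant pairs: %.2e /yr (p = %.2e)",
                trend_sig$fit$slope, trend_sig$fit$p))

utils::write.csv(fits, "results/corr_trajectories.csv", row.names = FALSE)
utils::write.csv(trajectory_summary_table(fits$class, nrow(fits)),
                 "results/table_corr_classes.csv", row.names = FALSE)
utils::write.csv(volcano_data(fits), "results/volcano_correlations.csv",
                 row.names = FALSE)
utils::write.csv(cbind(trend_all$series, which = "all"),
                 "results/mean_abs_corr_series.csv", row.names = FALSE)
saveRDS(ct, "scratch/corr_panel.rds")
message("wrote results/corr_trajectories.csv and companions")
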