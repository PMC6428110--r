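#!/usr/bin/env Rscript
# Stage 2 — preprocess the raw cohort to an analysis matrix.
#
# Iterative completeness extraction, >0.9-|r| redundancy filter,
# gaussianizing transforms and survey-weighted standardization; then the
# weighted linear association of every biomarker with age.

suppressPackageStartupMessages(library(agecodep))

cohort <- utils::read.csv("scratch/cohort.csv", stringsAsFactors = FALSE)
message(sprintf("raw: %d x %d biomarkers", nrow(cohort),
                length(biomarker_names(cohort))))

pp <- preprocess(cohort)
rep_ <- pp$reports
message(sprintf("completeness: dropped %d samples, %d biomarkers",
                length(rep_$complete_matrix$dropped_samples),
                length(rep_$complete_matrix$dropped_biomarkers)))
message("redundancy filter dropped: ",
        paste(rep_$drop_redundant$dropped_biomarkers, collapse = ", "),
        " (", paste(rep_$drop_redundant$reason, collapse = "; "), ")")
tr <- table(rep_$gaussianize$transform_per_biomarker)
message("transforms chosen: ",
        paste(names(tr), tr, sep = "=", collapse = ", "))

assoc <- biomarker_age_association(pp$table)
assoc <- assoc[order(assoc$slope_x100), ]
message(sprintf("%d of %d biomarkers significantly associated with age",
                sum(assoc$corrected_p < 0.05), nrow(assoc)))

utils::write.csv(pp$table, "scratch/matrix.csv", row.names = FALSE)
utils::write.csv(assoc, "results/table_age_associations.csv",
                 row.names = FALSE)
jsonlite::write_json(
  list(
    dropped_samples = rep_$complete_matrix$dropped_samples,
    dropped_biomarkers = c(rep_$complete_matrix$dropped_biomarkers,
                           rep_$drop_redundant$dropped_biomarkers),
    transforms = as.list(rep_$gaussianize$transform_per_biomarker),
    weighted_means = as.list(rep_$weighted_standardize$weighted_means),
    weighted_sds = as.list(rep_$weighted_standardize$weighted_sds)
  ),
  "results/preprocess_report.json", auto_unbox = TRUE, pretty = TRUE
)
message("wrote scratch/matrix.csv, results/table_age_associations.csv, ",
        "results/preprocess_report.json")
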