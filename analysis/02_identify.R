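#!/usr/bin/env Rscript
# Step 2 — identify candidate pneumonitis index reports.
#
# Runs the two-stage keyword cascade over the report stream, keeps only
# patients with a qualifying ICI or thoracic-field radiotherapy exposure
# before the scan, and collapses repeat scans within 6 months into single
# episodes.  Writes the candidate index reports and the funnel counts.

suppressPackageStartupMessages(library(pneumotrace))

cohort <- read_cohort("results/synth")
rules <- term_config()

res <- identify_cases(cohort$reports, cohort$ici, cohort$rt, rules)

cat("Identification funnel:\n")
print(res$funnel)

cand <- res$index_reports
utils::write.csv(
  cand[, c("report_id", "patient_id", "scan_date", "stage1_terms",
           "stage2_terms", "episode")],
  "results/candidates.csv", row.names = FALSE)
utils::write.csv(data.frame(stage = names(res$funnel),
                            count = as.integer(res$funnel)),
                 "results/funnel.csv", row.names = FALSE)
cat("Wrote", nrow(cand), "candidate episodes to results/candidates.csv\n")
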