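#!/usr/bin/env Rscript
# Step 4 — 16-week resource utilisation and the severity-strata contrast.
#
# Extracts each case's consultant follow-up, CT and MDT activity in the 112
# days after diagnosis plus admissions and work-up flags, then compares
# follow-up clinic counts between grade 1 and grade 2-4 cases with a Welch
# unpaired t-test (grade 5 excluded: follow-up is truncated by death).

suppressPackageStartupMessages(library(pneumotrace))

cohort <- read_cohort("results/synth")
cases <- utils::read.csv("results/cases.csv")
cases$diagnosis_date <- as.Date(cases$diagnosis_date)
cases <- tibble::as_tibble(cases)

profiles <- extract_profiles(cases, cohort$clinical)
utils::write.csv(profiles, "results/profiles.csv", row.names = FALSE)

sympt <- cases$grade >= 2
cat("Resource use among", sum(sympt), "symptomatic cases:\n")
for (flag in c("referral", "bal", "pft")) {
  cat(sprintf("  %-9s %5.1f%%\n", flag, 100 * mean(profiles[[flag]][sympt])))
}
cat(sprintf("  admitted  %5.1f%%  (mean %.1f nights when admitted)\n",
            100 * mean(profiles$hospital_nights[sympt] > 0),
            mean(profiles$hospital_nights[sympt][
              profiles$hospital_nights[sympt] > 0])))

cmp <- compare_strata(profiles, cases$grade)
cat(sprintf(paste0("Clinic visits, grade 2-4 vs 1: diff %.2f ",
                   "(95%% CI %.2f-%.2f), t = %.2f, p = %.2g\n"),
            cmp$diff, cmp$ci_lower, cmp$ci_upper, cmp$statistic,
            cmp$p_value))
utils::write.csv(cmp, "results/strata_comparison.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  df <- data.frame(stratum = ifelse(cases$grade == 1, "grade 1",
                                    ifelse(cases$grade <= 4, "grade 2-4",
                                           "grade 5")),
                   visits = profiles$clinic_visits)
  p <- ggplot(df[df$stratum != "grade 5", ],
              aes(stratum, visits, fill = stratum)) +
    geom_boxplot(show.legend = FALSE) +
    labs(x = NULL, y = "consultant follow-up visits / 16 weeks") +
    theme_minimal()
  ggsave("results/fig_clinic_visits.png", p, width = 4, height = 3, dpi = 150)
}
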