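#!/usr/bin/env Rscript
# Step 5 — health-economics model.
#
# Prices the average symptomatic pneumonitis case with the ten-line
# weighted unit-cost model (NHS reference costs 2019/20 + BNF), then
# extrapolates to the observed symptomatic case count over the six-year
# window and runs simple sensitivity scenarios.

suppressPackageStartupMessages(library(pneumotrace))

model <- nhs_cost_table()
cases <- utils::read.csv("results/cases.csv")
n_sympt <- sum(cases$grade >= 2)

cat("Cost model (GBP):\n")
print(data.frame(resource = model$resource, weight = model$weight,
                 unit = model$unit_cost,
                 line = line_cost(model, display = TRUE)))

cc <- cohort_cost(model, n_cases = n_sympt, n_years = 6)
cat(sprintf("\nPer symptomatic case: GBP %.2f\n",
            round_half_up(cc$per_patient, 2)))
cat(sprintf("Cohort total (%d cases over 6 years): GBP %.2f\n",
            n_sympt, round_half_up(cc$total, 2)))
cat(sprintf("Annual cost: GBP %.2f\n", round_half_up(cc$annual, 2)))

scen <- data.frame(
  scenario = c("extra respiratory follow-up", "PFTs for every case",
               "admissions halved", "all unit costs +10%"),
  resource = c("FU respiratory appointment", "PFT",
               "Hospital admission (nights)", NA),
  weight_mult = c(2, 1 / 0.417, 0.5, 1),
  cost_mult = c(1, 1, 1, 1.1))
sens <- cost_sensitivity(model, scen)
cat("\nSensitivity (per-case GBP):\n")
print(as.data.frame(sens))

utils::write.csv(sens, "results/sensitivity.csv", row.names = FALSE)
jsonlite::write_json(
  list(n_symptomatic = n_sympt,
       per_patient = round_half_up(cc$per_patient, 2),
       total = round_half_up(cc$total, 2),
       annual = round_half_up(cc$annual, 2)),
  "results/costs.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/costs.json and results/sensitivity.csv\n")
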