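# End-to-end orchestration: identification funnel, incidence summaries and
# the assembled pipeline result.

#' Incidence table from case counts and treated denominators
#'
#' Percentage incidence `100 * cases / denominator`, displayed with
#' half-up rounding.  Groups with a zero denominator are dropped with a
#' warning.
#'
#' @param cases Named integer vector of case counts.
#' @param denominators Named integer vector of treated-patient
#'   denominators; names must cover those of `cases`.
#' @param digits Decimal places displayed (default 2).
#' @return Tibble with `group`, `cases`, `denominator`, `incidence_pct`
#'   (displayed) and `fraction` (raw).
#' @examples
#' incidence_table(c(ICI = 85), c(ICI = 1565))$incidence_pct # 5.43
#' @export
incidence_table <- function(cases, denominators, digits = 2) {
  stopifnot(all(names(cases) %in% names(denominators)))
  denominators <- denominators[names(cases)]
  zero <- denominators == 0
  if (any(zero)) {
    warning("dropping group(s) with zero denominator: ",
            paste(names(cases)[zero], collapse = ", "), call. = FALSE)
    cases <- cases[!zero]
    denominators <- denominators[!zero]
  }
  tibble::tibble(group = names(cases), cases = as.integer(unname(cases)),
                 denominator = as.integer(unname(denominators)),
                 incidence_pct = unname(pct(cases, denominators, digits)),
                 fraction = unname(as.numeric(cases / denominators)))
}

#' Run the full synthetic-EHR analysis pipeline
#'
#' Executes identification, attribution, grading, resource extraction, the
#' severity-strata comparison and the cost model over one cohort (generated
#' or read from disk), and assembles the identification funnel.
#'
#' @param cohort Record streams as produced by [generate_cohort()] or
#'   [read_cohort()] (element `truth` is ignored here and may be absent).
#' @param config A [term_config()].
#' @param windows An [attribution_windows()].
#' @param cost_model A `cost_model`; default [nhs_cost_table()].
#' @param n_years Study duration in years used for the cost extrapolation.
#' @param exclusions Optional manually-excluded `report_id`s.
#' @return List with `funnel` (named counts: reports, stage1, stage2,
#'   treatment, validated, episodes, attributed, symptomatic), `cases`,
#'   `excluded`, `profiles`, `comparison` (grade 2-4 vs 1 clinic visits,
#'   `NULL` if a stratum is too small), `costs` (per-patient / cohort /
#'   annual, using the observed symptomatic count) and `incidence` (by
#'   attributed aetiology over treated-patient denominators).
#' @export
run_pipeline <- function(cohort, config = term_config(),
                         windows = attribution_windows(),
                         cost_model = nhs_cost_table(), n_years = 6,
                         exclusions = NULL) {
  ident <- identify_cases(cohort$reports, cohort$ici, cohort$rt, config,
                          exclusions)
  attributed <- attribute_aetiology(ident$index_reports, cohort$ici,
                                    cohort$rt, config, windows)
  built <- build_cases(attributed, cohort$clinical)
  cases <- built$cases
  profiles <- if (nrow(cases)) extract_profiles(cases, cohort$clinical)
    else NULL
  comparison <- tryCatch(compare_strata(profiles, cases$grade),
                         error = function(e) NULL)
  n_sympt <- sum(cases$grade >= 2)
  costs <- cohort_cost(cost_model, n_cases = n_sympt, n_years = n_years)

  treated_ici <- unique(cohort$ici$patient_id)
  treated_rt <- unique(
    cohort$rt$patient_id[tolower(cohort$rt$site) %in% config$rt_sites])
  sympt <- cases[cases$grade >= 2, ]
  denom <- c(ICI = length(treated_ici), RT = length(treated_rt),
             both = length(intersect(treated_ici, treated_rt)))
  counts <- c(ICI = sum(sympt$aetiology == "ICI"),
              RT = sum(sympt$aetiology == "RT"),
              both = sum(sympt$aetiology == "both"))
  incidence <- incidence_table(counts, denom)

  funnel <- c(ident$funnel, attributed = nrow(cases), symptomatic = n_sympt)
  stopifnot(all(diff(funnel) <= 0))  # counts never increase along the funnel
  list(funnel = funnel, cases = cases, excluded = built$excluded,
       profiles = profiles, comparison = comparison, costs = costs,
       incidence = incidence)
}
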