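# Weighted unit-cost model of symptomatic pneumonitis: per-line, per-patient
# and cohort-level costs from an NHS reference-cost table.

#' Parse a weight expression
#'
#' Cost-table weights may be plain numbers (`"0.417"`) or products
#' (`"10.5*0.39"`, expected nights times admission probability).  Only
#' numeric factors joined by `*` are admitted.
#'
#' @param x Character vector of weight expressions.
#' @return Numeric vector of evaluated weights.
#' @export
parse_weight <- function(x) {
  vapply(strsplit(gsub("[ x\u00d7]", "*", x), "*", fixed = TRUE),
         function(parts) {
           parts <- parts[nzchar(parts)]
           vals <- suppressWarnings(as.numeric(parts))
           if (length(vals) == 0 || anyNA(vals)) {
             stop("invalid weight expression: ", paste(parts, collapse = "*"),
                  call. = FALSE)
           }
           prod(vals)
         }, numeric(1))
}

#' Read a unit-cost table
#'
#' Reads a CSV with columns `resource`, `weight_expr`, `unit_cost`, `code`
#' and evaluates the weight expressions.  Negative weights or unit costs
#' are rejected.
#'
#' @param path CSV file path.
#' @return Tibble with class `cost_model`: `resource`, `weight_expr`,
#'   `weight`, `unit_cost`, `code`.
#' @export
read_cost_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("resource", "weight_expr", "unit_cost", "code") %in%
                  names(df)))
  df$weight <- parse_weight(as.character(df$weight_expr))
  if (any(df$weight < 0) || any(df$unit_cost < 0)) {
    stop("negative weight or unit cost in cost table", call. = FALSE)
  }
  out <- tibble::as_tibble(df[, c("resource", "weight_expr", "weight",
                                  "unit_cost", "code")])
  class(out) <- c("cost_model", class(out))
  out
}

#' Write a cost model back to its CSV format
#'
#' Round-trips through [read_cost_table()] without changing any total.
#'
#' @param model A `cost_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_table <- function(model, path) {
  utils::write.csv(model[, c("resource", "weight_expr", "unit_cost", "code")],
                   path, row.names = FALSE)
  invisible(path)
}

#' The NHS 2019/20 reference-cost model for symptomatic pneumonitis
#'
#' Ten resource lines (respiratory appointments, bronchoscopy, PFT, CT,
#' MDT, oncology follow-up, hospital and critical-care admission nights,
#' immunosuppressive rescue therapy) with usage weights observed in a
#' symptomatic pneumonitis cohort and 2019/20 NHS reference / BNF unit
#' costs.  Admission lines carry product weights, expected nights times the
#' proportion of symptomatic cases admitted: 10.5 nights x 0.39 for
#' hospital and 6.5 nights x 0.07 for critical care.  (Some printed
#' renditions of this table transpose the two probability factors; the
#' 0.39-hospital/0.07-CCU assignment is the one consistent with the
#' admission percentages and with every line total.)
#'
#' @return A `cost_model` tibble (see [read_cost_table()]).
#' @examples
#' per_patient_cost(nhs_cost_table()) # 3932.33...
#' @export
nhs_cost_table <- function() {
  read_cost_table(system.file("extdata", "nhs_costs_2019_20.csv",
                              package = "pneumotrace", mustWork = TRUE))
}

#' Per-line expected cost
#'
#' Weight times unit cost per line.  Unrounded values are used in every
#' aggregate; use `display = TRUE` for the conventional half-up 2-decimal
#' currency display.
#'
#' @param model A `cost_model`.
#' @param display Round half-up to 2 decimal places?
#' @return Numeric vector of line costs (GBP).
#' @export
line_cost <- function(model, display = FALSE) {
  out <- model$weight * model$unit_cost
  if (display) round_half_up(out, 2) else out
}

#' Expected healthcare cost per symptomatic pneumonitis case
#'
#' Sum of unrounded line costs.
#'
#' @param model A `cost_model`.
#' @return Per-patient cost in GBP (unrounded).
#' @export
per_patient_cost <- function(model) {
  stopifnot(nrow(model) >= 1)
  sum(line_cost(model))
}

#' Cohort and annual cost extrapolation
#'
#' Multiplies the unrounded per-patient cost by the number of symptomatic
#' cases and divides by the number of study years.  Rounding only the final
#' figures (half-up, 2 dp) reproduces printed cohort totals that a
#' pre-rounded per-patient sum would miss.
#'
#' @param model A `cost_model`.
#' @param n_cases Number of symptomatic cases (>= 0).
#' @param n_years Study duration in years (> 0).
#' @return List with unrounded `per_patient`, `total`, `annual`.
#' @examples
#' cohort_cost(nhs_cost_table(), n_cases = 139, n_years = 6)
#' @export
cohort_cost <- function(model, n_cases, n_years) {
  stopifnot(n_cases >= 0)
  if (n_years <= 0) stop("n_years must be positive", call. = FALSE)
  pp <- per_patient_cost(model)
  list(per_patient = pp, total = pp * n_cases, annual = pp * n_cases / n_years)
}

#' One-way sensitivity analysis over the cost model
#'
#' Recomputes the per-patient cost under multiplicative and/or additive
#' perturbations of individual lines (or all lines when `resource` is
#' `NA`).  The baseline scenario always equals [per_patient_cost()].
#'
#' @param model A `cost_model`.
#' @param scenarios Data frame with columns `scenario`, `resource` (`NA`
#'   for all lines), and any of `weight_mult`, `cost_mult`, `weight_add`
#'   (defaults 1, 1, 0).
#' @return Tibble with `scenario`, `per_patient` (unrounded) and
#'   `delta` from baseline; the baseline row comes first.
#' @export
cost_sensitivity <- function(model, scenarios) {
  base <- per_patient_cost(model)
  if (is.null(scenarios$weight_mult)) scenarios$weight_mult <- 1
  if (is.null(scenarios$cost_mult)) scenarios$cost_mult <- 1
  if (is.null(scenarios$weight_add)) scenarios$weight_add <- 0
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    m <- model
    sel <- if (is.na(scenarios$resource[i])) rep(TRUE, nrow(m)) else
      m$resource == scenarios$resource[i]
    if (!any(sel)) {
      stop("unknown resource in scenario: ", scenarios$resource[i],
           call. = FALSE)
    }
    m$weight[sel] <- m$weight[sel] * scenarios$weight_mult[i] +
      scenarios$weight_add[i]
    m$unit_cost[sel] <- m$unit_cost[sel] * scenarios$cost_mult[i]
    tibble::tibble(scenario = scenarios$scenario[i],
                   per_patient = per_patient_cost(m))
  })
  out <- rbind(tibble::tibble(scenario = "baseline", per_patient = base),
               do.call(rbind, rows))
  out$delta <- out$per_patient - base
  out
}

#' Unit cost of a drug course from pack price
#'
#' Total course dose divided into packs, priced per pack; used to validate
#' the immunosuppressive-rescue line of the cost table (a 3,500 mg
#' infliximab course at 377 GBP per 100 mg pack).
#'
#' @param total_mg Total course dose in mg.
#' @param pack_mg Pack size in mg.
#' @param pack_cost Cost per pack in GBP.
#' @return Course cost in GBP.
#' @examples
#' drug_course_cost(3500, 100, 377) # 13195
#' @export
drug_course_cost <- function(total_mg = 3500, pack_mg = 100,
                             pack_cost = 377) {
  stopifnot(total_mg >= 0, pack_mg > 0, pack_cost >= 0)
  total_mg / pack_mg * pack_cost
}
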