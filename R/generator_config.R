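# Configuration object for the synthetic EHR generator.

#' Configuration for the synthetic EHR cohort generator
#'
#' Bundles every tunable of [generate_cohort()] with defaults matching the
#' study conditions the pipeline is designed for: a six-year scan window,
#' a 5% all-cause pneumonitis prevalence split ICI : RT : mixed in the
#' ratio 85 : 44 : 10 among cases, a five-grade severity mass of
#' (109, 107, 15, 4, 13)/248, onset laws from [onset_defaults()], and
#' per-resource usage probabilities for symptomatic cases.
#'
#' @param n_patients Number of patients to simulate.
#' @param study_start,study_end Scan-date window (Date).
#' @param p_aetiology Named probabilities over `ICI`, `RT`, `both`, `none`;
#'   must sum to 1 within 1e-9.
#' @param severity_pmf Probability mass over CTCAE grades 1-5; sums to 1
#'   within 1e-9.
#' @param onset Per-aetiology onset parameters, see [onset_defaults()].
#' @param resource_probs Named per-resource usage probabilities among
#'   symptomatic (grade >= 2) cases: `antibiotics`, `steroids`,
#'   `cotrimoxazole`, `immunosuppressive`, `referral`, `bal`, `pft`,
#'   `hospital`, `ccu`, `infection` (superadded infection flag).
#' @param clinic_mean Mean 16-week consultant follow-up visit counts, named
#'   `grade1` and `grade2plus`.  Defaults 4.40 and 6.61 place the expected
#'   group difference at 2.21 visits.
#' @param ct_mean,mdt_mean Mean 16-week CT thorax and MDT discussion counts
#'   (equal across severity strata).
#' @param p_treated_noncase Named probabilities that a patient without
#'   pneumonitis has ICI, RT, both, or no treatment history.
#' @param distractor_rate Fraction of non-case patients whose report carries
#'   flag terms without true pneumonitis (query-only requests, untreated
#'   term matches, negated mentions, infective pneumonia).
#' @param include_negated Whether negated-mention / infective-mimic
#'   distractors (the ones the keyword cascade cannot reject) are generated.
#' @param p_followup_scan Probability a true case has an additional
#'   pneumonitis-describing scan 30-150 days after the index scan (exercises
#'   episode deduplication).
#' @param p_rechallenge Probability an ICI-attributed case is re-challenged
#'   after the diagnosis.
#' @param rechallenge_gap Truncated log-normal parameters (days) for the
#'   treatment time lost between hold and re-introduction: mean 73, range
#'   11-275.
#' @param seed Integer RNG seed; a fixed seed makes the generated streams
#'   byte-identical across runs.
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(n_patients = 200, seed = 7)
#' cfg$p_aetiology
#' @export
generator_config <- function(n_patients = 5000,
                             study_start = as.Date("2015-01-01"),
                             study_end = as.Date("2020-12-31"),
                             p_aetiology = c(ICI = 0.05 * 85 / 139,
                                             RT = 0.05 * 44 / 139,
                                             both = 0.05 * 10 / 139,
                                             none = 0.95),
                             severity_pmf = c(109, 107, 15, 4, 13) / 248,
                             onset = onset_defaults(),
                             resource_probs = c(antibiotics = 0.568,
                                                steroids = 0.964,
                                                cotrimoxazole = 0.295,
                                                immunosuppressive = 0.043,
                                                referral = 0.417,
                                                bal = 0.237,
                                                pft = 0.086,
                                                hospital = 0.388,
                                                ccu = 0.072,
                                                infection = 0.18),
                             clinic_mean = c(grade1 = 4.40,
                                             grade2plus = 6.61),
                             ct_mean = 1, mdt_mean = 1,
                             p_treated_noncase = c(ICI = 0.30, RT = 0.20,
                                                   both = 0.05, none = 0.45),
                             distractor_rate = 0.10,
                             include_negated = TRUE,
                             p_followup_scan = 0.40,
                             p_rechallenge = 0.346,
                             rechallenge_gap = list(mean_days = 73,
                                                    min_days = 11,
                                                    max_days = 275,
                                                    sdlog = 0.8),
                             seed = 1L) {
  check_pmf <- function(p, field, nms = NULL) {
    if (any(p < 0) || any(p > 1)) {
      stop("configuration error in '", field, "': probabilities must lie in [0, 1]",
           call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop("configuration error in '", field, "': probabilities sum to ",
           format(sum(p), digits = 12), ", not 1", call. = FALSE)
    }
    if (!is.null(nms) && !identical(sort(names(p)), sort(nms))) {
      stop("configuration error in '", field, "': names must be ",
           paste(nms, collapse = ", "), call. = FALSE)
    }
  }
  stopifnot(length(n_patients) == 1, n_patients >= 1,
            inherits(study_start, "Date"), inherits(study_end, "Date"),
            study_end > study_start)
  check_pmf(p_aetiology, "p_pneumonitis_by_aetiology",
            c("ICI", "RT", "both", "none"))
  check_pmf(severity_pmf, "severity_pmf")
  if (length(severity_pmf) != 5) {
    stop("configuration error in 'severity_pmf': need mass for grades 1-5",
         call. = FALSE)
  }
  check_pmf(p_treated_noncase, "p_treated_noncase",
            c("ICI", "RT", "both", "none"))
  if (any(resource_probs < 0 | resource_probs > 1)) {
    stop("configuration error in 'resource_probs': values outside [0, 1]",
         call. = FALSE)
  }
  stopifnot(distractor_rate >= 0, distractor_rate <= 1,
            p_followup_scan >= 0, p_followup_scan <= 1,
            p_rechallenge >= 0, p_rechallenge <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 study_start = study_start, study_end = study_end,
                 p_aetiology = p_aetiology, severity_pmf = severity_pmf,
                 onset = onset, resource_probs = resource_probs,
                 clinic_mean = clinic_mean, ct_mean = ct_mean,
                 mdt_mean = mdt_mean,
                 p_treated_noncase = p_treated_noncase,
                 distractor_rate = distractor_rate,
                 include_negated = include_negated,
                 p_followup_scan = p_followup_scan,
                 p_rechallenge = p_rechallenge,
                 rechallenge_gap = rechallenge_gap,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic EHR generator configuration\n")
  cat("  patients:     ", x$n_patients, "\n")
  cat("  scan window:  ", format(x$study_start), "..", format(x$study_end), "\n")
  cat("  P(aetiology): ", paste(sprintf("%s=%.4f", names(x$p_aetiology),
                                        x$p_aetiology), collapse = " "), "\n")
  cat("  severity pmf: ", paste(sprintf("%.3f", x$severity_pmf),
                                collapse = " "), "(grades 1-5)\n")
  cat("  distractors:  ", x$distractor_rate,
      if (x$include_negated) "(negated mentions on)" else "(negated mentions off)",
      "\n")
  cat("  seed:         ", x$seed, "\n")
  invisible(x)
}
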