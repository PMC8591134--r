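# Synthetic EHR generator: emits radiology-report, ICI-administration,
# radiotherapy-course and clinical-event streams with ground-truth labels,
# so the identification/attribution/grading/costing pipeline is testable
# without patient data.

# --- report text banks ------------------------------------------------------

.case_request <- c(
  "? pneumonitis - new dyspnoea and cough on systemic therapy",
  "Response assessment CT chest.",
  "Restaging CT thorax. Increasing breathlessness."
)

.case_body <- list(
  ICI = c(
    paste("New bilateral ground glass opacification with septal thickening.",
          "Appearances are in keeping with pneumonitis, likely related to",
          "recent immunotherapy treatment."),
    paste("Diffuse ground glass infiltrates throughout both lungs,",
          "consistent with drug induced pulmonary toxicity.")
  ),
  RT = c(
    paste("Patchy consolidation and ground glass change conforming to the",
          "radiotherapy treatment field, in keeping with radiation",
          "pneumonitis."),
    paste("New diffuse interstitial change within the irradiated lung,",
          "suggestive of radiation induced lung injury.")
  ),
  both = c(
    paste("Widespread ground glass change and new infiltrates; differential",
          "includes drug related pneumonitis and radiation pneumonitis",
          "following recent treatment.")
  )
)

.followup_body <- paste("Improving ground glass change with residual",
                        "pneumonitis following steroid treatment.")

.clean_request <- "Surveillance CT."
.clean_body <- paste("Stable thoracic appearances. No focal consolidation.",
                     "The lungs remain clear.")

.distractor <- list(
  request_only = list(
    request = "? pneumonitis - please assess",
    body = paste("The lungs are clear with no focal consolidation.",
                 "Stable appearances. No new abnormality.")
  ),
  no_treatment = list(
    request = "CT thorax.",
    body = paste("Diffuse ground glass change raising the possibility of",
                 "pneumonitis; clinical correlation advised.")
  ),
  negated = list(
    request = "Follow up CT.",
    body = paste("No evidence of pneumonitis. Stable post treatment",
                 "appearances with no new ground glass change.")
  ),
  infection = list(
    request = "Pyrexia and productive cough.",
    body = paste("Right lower lobe consolidation in keeping with infective",
                 "pneumonia. Diffuse bronchial wall thickening.")
  )
)

.ici_drug_probs <- c(Pembrolizumab = 0.36, Nivolumab = 0.30,
                     Atezolizumab = 0.12, Durvalumab = 0.10,
                     Ipilimumab = 0.06, Avelumab = 0.06)
.both_drug_probs <- c(Durvalumab = 0.6, Pembrolizumab = 0.3,
                      Atezolizumab = 0.1)
.rt_site_probs <- c(thorax = 0.58, breast = 0.12, `chest wall` = 0.08,
                    vertebrae = 0.10, `upper abdomen` = 0.07, neck = 0.05)
.rt_schedules <- data.frame(
  dose_gy = c(20, 30, 39, 60, 66, 55),
  fractions = c(5, 10, 13, 30, 33, 20),
  palliative = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
)

# inverse-CDF sampler for an arbitrary truncated log-normal parameter list
sample_trunc_lnorm_days <- function(n, par) {
  fit <- fit_onset_lnorm(par)
  pa <- stats::plnorm(fit$min_days, fit$meanlog, fit$sdlog)
  pb <- stats::plnorm(fit$max_days, fit$meanlog, fit$sdlog)
  x <- stats::qlnorm(stats::runif(n, pa, pb), fit$meanlog, fit$sdlog)
  as.integer(pmin(pmax(round(x), ceiling(fit$min_days)),
                  floor(fit$max_days)))
}

sample_days <- function(n, from, to) {
  if (n == 0) return(integer(0))
  as.integer(sample(seq.int(from, to), n, replace = TRUE))
}

# gamma-distributed whole-day delay with given mean, clipped to [lo, hi]
sample_delay <- function(n, mean, lo, hi, shape = 1.3) {
  x <- round(stats::rgamma(n, shape = shape, scale = mean / shape))
  as.integer(pmin(pmax(x, lo), hi))
}

#' Generate a synthetic EHR cohort with ground truth
#'
#' Simulates `config$n_patients` patients and emits the four record streams
#' the identification pipeline consumes, plus per-patient ground truth:
#'
#' * `reports`: CT thorax reports (`report_id`, `patient_id`, `scan_date`,
#'   `request_text`, `body_text`).  True cases receive an index report whose
#'   body embeds at least one stage-1 and one stage-2 phrase, optionally a
#'   later pneumonitis-describing follow-up scan inside the deduplication
#'   window; everyone else receives a clean surveillance report or, at rate
#'   `distractor_rate`, a distractor (query-only request, untreated term
#'   match, negated mention, or infective pneumonia mimic).
#' * `ici`: ICI administrations (`patient_id`, `drug`, `admin_date`), one
#'   cycle every 21 days from treatment start to diagnosis, plus
#'   re-challenge cycles for re-challenged cases.
#' * `rt`: radiotherapy courses (`patient_id`, `site`, `dose_gy`,
#'   `fractions`, `first_fraction_date`).
#' * `clinical`: dated clinical/resource events (`patient_id`, `event_type`,
#'   `event_date`, `value`): severity flags (symptoms,
#'   oxygen_or_admission, intubation, death), 16-week activity
#'   (clinic_visit, ct_thorax, mdt), investigations and treatments
#'   (resp_review, bal, pft, steroids, antibiotics, cotrimoxazole,
#'   immunosuppressive, infection) and admissions (admission,
#'   ccu_admission; `value` = nights).
#' * `truth`: per-patient labels (`case`, `aetiology`, `grade`,
#'   `diagnosis_date`, `onset_days`, `distractor`, `rechallenged`,
#'   `rechallenge_gap`).
#'
#' Treatment timing honours the attribution windows by construction: ICI
#' cases always have an administration 1-21 days before diagnosis and no
#' radiotherapy; RT cases have the first fraction `onset` days (at most 8
#' months) before diagnosis and no ICI; mixed cases satisfy both windows.
#' All randomness flows from `config$seed`; a fixed seed gives
#' byte-identical streams.
#'
#' @param config A [generator_config()].
#' @return Named list of five tibbles: `reports`, `ici`, `rt`, `clinical`,
#'   `truth`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 300, seed = 42))
#' table(cohort$truth$aetiology)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%05d", seq_len(n))
  window_days <- as.integer(config$study_end - config$study_start)

  aet <- sample(names(config$p_aetiology), n, replace = TRUE,
                prob = config$p_aetiology)
  is_case <- aet != "none"
  grade <- rep(NA_integer_, n)
  grade[is_case] <- sample(1:5, sum(is_case), replace = TRUE,
                           prob = config$severity_pmf)

  diag_date <- rep(as.Date(NA), n)
  diag_date[is_case] <- config$study_start +
    sample_days(sum(is_case), 0, window_days)

  onset <- rep(NA_integer_, n)
  for (a in c("ICI", "RT", "both")) {
    idx <- which(aet == a)
    if (length(idx)) onset[idx] <- sample_onset(length(idx), a, config$onset)
  }

  # --- treatments -----------------------------------------------------------
  ici_pid <- character(0); ici_drug <- character(0); ici_date <- as.Date(character(0))
  rt_pid <- character(0); rt_site <- character(0)
  rt_dose <- numeric(0); rt_fx <- integer(0); rt_date <- as.Date(character(0))

  add_ici_course <- function(ids, start, end, drug) {
    # one administration every 21 days from start, last one strictly before end
    k <- pmax(1L, as.integer(ceiling(as.numeric(end - start) / 21)))
    off <- 21L * (sequence(k) - 1L)
    list(pid = rep(ids, k), drug = rep(drug, k),
         date = rep(start, k) + off)
  }

  ici_case <- which(aet %in% c("ICI", "both"))
  if (length(ici_case)) {
    start <- diag_date[ici_case] - onset[ici_case]
    drug <- ifelse(aet[ici_case] == "both",
                   sample(names(.both_drug_probs), length(ici_case),
                          replace = TRUE, prob = .both_drug_probs),
                   sample(names(.ici_drug_probs), length(ici_case),
                          replace = TRUE, prob = .ici_drug_probs))
    crs <- add_ici_course(pid[ici_case], start, diag_date[ici_case], drug)
    ici_pid <- c(ici_pid, crs$pid); ici_drug <- c(ici_drug, crs$drug)
    ici_date <- c(ici_date, crs$date)
  }

  rt_case <- which(aet %in% c("RT", "both"))
  if (length(rt_case)) {
    gap <- ifelse(aet[rt_case] == "RT", onset[rt_case],
                  sample_days(length(rt_case), 8, 360))
    sched <- ifelse(stats::runif(length(rt_case)) < 0.18,
                    sample(which(.rt_schedules$palliative), length(rt_case),
                           replace = TRUE),
                    sample(which(!.rt_schedules$palliative), length(rt_case),
                           replace = TRUE))
    rt_pid <- c(rt_pid, pid[rt_case])
    rt_site <- c(rt_site, sample(names(.rt_site_probs), length(rt_case),
                                 replace = TRUE, prob = .rt_site_probs))
    rt_dose <- c(rt_dose, .rt_schedules$dose_gy[sched])
    rt_fx <- c(rt_fx, .rt_schedules$fractions[sched])
    rt_date <- c(rt_date, diag_date[rt_case] - gap)
  }

  # treatment histories for non-case patients (realistic denominators)
  noncase <- which(!is_case)
  trt_nc <- sample(names(config$p_treated_noncase), length(noncase),
                   replace = TRUE, prob = config$p_treated_noncase)
  first_trt <- rep(as.Date(NA), n)

  nc_ici <- noncase[trt_nc %in% c("ICI", "both")]
  if (length(nc_ici)) {
    start <- config$study_start - 180L +
      sample_days(length(nc_ici), 0, window_days + 120L)
    k <- 1L + stats::rpois(length(nc_ici), 7)
    drug <- sample(names(.ici_drug_probs), length(nc_ici), replace = TRUE,
                   prob = .ici_drug_probs)
    off <- 21L * (sequence(k) - 1L)
    ici_pid <- c(ici_pid, rep(pid[nc_ici], k))
    ici_drug <- c(ici_drug, rep(drug, k))
    ici_date <- c(ici_date, rep(start, k) + off)
    first_trt[nc_ici] <- start
  }
  nc_rt <- noncase[trt_nc %in% c("RT", "both")]
  if (length(nc_rt)) {
    ff <- config$study_start - 180L +
      sample_days(length(nc_rt), 0, window_days + 150L)
    qualifying <- stats::runif(length(nc_rt)) > 0.10
    site <- ifelse(qualifying,
                   sample(names(.rt_site_probs), length(nc_rt),
                          replace = TRUE, prob = .rt_site_probs),
                   sample(c("brain", "pelvis"), length(nc_rt),
                          replace = TRUE))
    sched <- sample(nrow(.rt_schedules), length(nc_rt), replace = TRUE)
    rt_pid <- c(rt_pid, pid[nc_rt]); rt_site <- c(rt_site, site)
    rt_dose <- c(rt_dose, .rt_schedules$dose_gy[sched])
    rt_fx <- c(rt_fx, .rt_schedules$fractions[sched])
    rt_date <- c(rt_date, ff)
    first_trt[nc_rt] <- pmin(first_trt[nc_rt], ff, na.rm = TRUE)
  }

  # --- reports --------------------------------------------------------------
  rep_pid <- character(0); rep_date <- as.Date(character(0))
  rep_req <- character(0); rep_body <- character(0)

  case_idx <- which(is_case)
  if (length(case_idx)) {
    req <- sample(.case_request, length(case_idx), replace = TRUE)
    body <- vapply(aet[case_idx],
                   function(a) sample(.case_body[[a]], 1L), character(1))
    rep_pid <- c(rep_pid, pid[case_idx])
    rep_date <- c(rep_date, diag_date[case_idx])
    rep_req <- c(rep_req, req); rep_body <- c(rep_body, body)

    fup <- case_idx[stats::runif(length(case_idx)) < config$p_followup_scan]
    if (length(fup)) {
      rep_pid <- c(rep_pid, pid[fup])
      rep_date <- c(rep_date, diag_date[fup] + sample_days(length(fup), 30, 150))
      rep_req <- c(rep_req, rep("Follow up CT chest.", length(fup)))
      rep_body <- c(rep_body, rep(.followup_body, length(fup)))
    }
  }

  # non-case patients: one surveillance or distractor report each
  distract <- rep("none", n)
  if (length(noncase)) {
    is_distr <- stats::runif(length(noncase)) < config$distractor_rate
    treated <- !is.na(first_trt[noncase])
    pool_treated <- c("request_only", "negated", "infection")
    if (!config$include_negated) pool_treated <- "request_only"
    dtype <- ifelse(is_distr,
                    ifelse(treated,
                           sample(pool_treated, length(noncase), replace = TRUE),
                           sample(c("request_only", "no_treatment"),
                                  length(noncase), replace = TRUE)),
                    "none")
    distract[noncase] <- dtype
    scan <- config$study_start + sample_days(length(noncase), 0, window_days)
    # distractors that must pass the treatment filter scan after treatment
    after_trt <- dtype %in% c("negated", "infection")
    scan[after_trt] <- first_trt[noncase[after_trt]] +
      sample_days(sum(after_trt), 30, 300)
    req <- rep(.clean_request, length(noncase))
    body <- rep(.clean_body, length(noncase))
    for (tp in names(.distractor)) {
      sel <- dtype == tp
      req[sel] <- .distractor[[tp]]$request
      body[sel] <- .distractor[[tp]]$body
    }
    rep_pid <- c(rep_pid, pid[noncase])
    rep_date <- c(rep_date, scan)
    rep_req <- c(rep_req, req); rep_body <- c(rep_body, body)
  }

  ord <- order(rep_pid, rep_date)
  reports <- tibble::tibble(
    report_id = sprintf("R%06d", seq_along(ord)),
    patient_id = rep_pid[ord], scan_date = rep_date[ord],
    request_text = rep_req[ord], body_text = rep_body[ord])

  # --- clinical events ------------------------------------------------------
  ev_pid <- character(0); ev_type <- character(0)
  ev_date <- as.Date(character(0)); ev_val <- numeric(0)
  add_events <- function(ids, type, dates, values = NA_real_) {
    ev_pid <<- c(ev_pid, ids)
    ev_type <<- c(ev_type, rep(type, length(ids)))
    ev_date <<- c(ev_date, dates)
    ev_val <<- c(ev_val, rep_len(values, length(ids)))
  }

  g <- function(gmin, gmax = gmin) {
    case_idx[grade[case_idx] >= gmin & grade[case_idx] <= gmax]
  }
  sym <- g(2, 5)
  add_events(pid[sym], "symptoms", diag_date[sym])
  sev <- g(3, 4)
  add_events(pid[sev], "oxygen_or_admission", diag_date[sev])
  add_events(pid[g(4)], "intubation", diag_date[g(4)])
  died <- g(5)
  add_events(pid[died], "death",
             diag_date[died] + sample_days(length(died), 6, 120))

  # 16-week activity counts for every case (window = 112 days)
  add_counts <- function(ids, type, mean_per_case) {
    k <- stats::rpois(length(ids), rep_len(mean_per_case, length(ids)))
    who <- rep(ids, k)
    if (length(who)) {
      add_events(pid[who], type,
                 rep(diag_date[ids], k) + sample_days(sum(k), 0, 111))
    }
  }
  cm <- ifelse(grade[case_idx] == 1, config$clinic_mean[["grade1"]],
               config$clinic_mean[["grade2plus"]])
  add_counts(case_idx, "clinic_visit", cm)
  add_counts(case_idx, "ct_thorax", config$ct_mean)
  add_counts(case_idx, "mdt", config$mdt_mean)

  # investigation / treatment / admission events for symptomatic cases
  bern <- function(ids, p) ids[stats::runif(length(ids)) < p]
  rp <- config$resource_probs
  for (spec in list(list("antibiotics", rp[["antibiotics"]], 0, 3),
                    list("steroids", rp[["steroids"]], 0, 3),
                    list("cotrimoxazole", rp[["cotrimoxazole"]], 0, 14),
                    list("immunosuppressive", rp[["immunosuppressive"]], 14, 60),
                    list("pft", rp[["pft"]], 7, 100),
                    list("infection", rp[["infection"]], 0, 3))) {
    ids <- bern(sym, spec[[2]])
    add_events(pid[ids], spec[[1]],
               diag_date[ids] + sample_days(length(ids), spec[[3]], spec[[4]]))
  }
  ids <- bern(sym, rp[["referral"]])
  add_events(pid[ids], "resp_review",
             diag_date[ids] + sample_delay(length(ids), 34, 0, 215))
  ids <- bern(sym, rp[["bal"]])
  add_events(pid[ids], "bal",
             diag_date[ids] + sample_delay(length(ids), 35, 1, 149))
  ids <- bern(sym, rp[["hospital"]])
  add_events(pid[ids], "admission",
             diag_date[ids] + sample_days(length(ids), 0, 28),
             pmin(pmax(stats::rpois(length(ids), 10.5), 1), 43))
  ids <- bern(sym, rp[["ccu"]])
  add_events(pid[ids], "ccu_admission",
             diag_date[ids] + sample_days(length(ids), 0, 28),
             pmin(pmax(stats::rpois(length(ids), 6.5), 1), 20))

  # --- ICI re-challenge -----------------------------------------------------
  rech <- rep(FALSE, n); rech_gap <- rep(NA_integer_, n)
  cand <- which(aet == "ICI" & grade < 5)
  cand <- cand[stats::runif(length(cand)) < config$p_rechallenge]
  if (length(cand)) {
    # hold date = last administration before diagnosis (by course construction)
    k <- pmax(1L, as.integer(ceiling(onset[cand] / 21)))
    hold <- diag_date[cand] - onset[cand] + 21L * (k - 1L)
    gap <- sample_trunc_lnorm_days(length(cand), config$rechallenge_gap)
    restart <- pmax(hold + gap, diag_date[cand] + 1L)
    rech[cand] <- TRUE
    rech_gap[cand] <- as.integer(restart - hold)
    drug <- vapply(pid[cand], function(p) ici_drug[ici_pid == p][1],
                   character(1))
    off <- 21L * (sequence(rep(3L, length(cand))) - 1L)
    ici_pid <- c(ici_pid, rep(pid[cand], each = 3))
    ici_drug <- c(ici_drug, rep(drug, each = 3))
    ici_date <- c(ici_date, rep(restart, each = 3) + off)
  }

  ord <- order(ici_pid, ici_date)
  ici <- tibble::tibble(patient_id = ici_pid[ord], drug = ici_drug[ord],
                        admin_date = ici_date[ord])
  ord <- order(rt_pid, rt_date)
  rt <- tibble::tibble(patient_id = rt_pid[ord], site = rt_site[ord],
                       dose_gy = rt_dose[ord], fractions = rt_fx[ord],
                       first_fraction_date = rt_date[ord])
  ord <- order(ev_pid, ev_date, ev_type)
  clinical <- tibble::tibble(patient_id = ev_pid[ord], event_type = ev_type[ord],
                             event_date = ev_date[ord], value = ev_val[ord])
  truth <- tibble::tibble(patient_id = pid, case = is_case, aetiology = aet,
                          grade = grade, diagnosis_date = diag_date,
                          onset_days = onset, distractor = distract,
                          rechallenged = rech, rechallenge_gap = rech_gap)

  list(reports = reports, ici = ici, rt = rt, clinical = clinical,
       truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Writes `reports.jsonl` (one JSON object per report, ISO-8601 dates) and
#' `ici.csv`, `rt.csv`, `clinical.csv`, `truth.csv` into `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "reports.jsonl"), "w")
  on.exit(close(con))
  apply(cohort$reports, 1L, function(r) {
    writeLines(jsonlite::toJSON(as.list(r), auto_unbox = TRUE), con)
  })
  for (nm in c("ici", "rt", "clinical", "truth")) {
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `reports.jsonl` and the CSV streams.
#' @return Named list of tibbles as produced by [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  lines <- readLines(file.path(dir, "reports.jsonl"))
  reports <- jsonlite::stream_in(textConnection(lines), verbose = FALSE)
  reports$scan_date <- as.Date(reports$scan_date)
  out <- list(reports = tibble::as_tibble(reports))
  date_cols <- list(ici = "admin_date", rt = "first_fraction_date",
                    clinical = "event_date", truth = "diagnosis_date")
  for (nm in names(date_cols)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) next
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df[[date_cols[[nm]]]] <- as.Date(df[[date_cols[[nm]]]])
    out[[nm]] <- tibble::as_tibble(df)
  }
  out
}
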