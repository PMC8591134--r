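# Aetiology attribution: look-back treatment windows before the diagnosis
# date, and treatment-interruption (lost time) arithmetic.

#' Attribution look-back windows
#'
#' A pneumonitis episode is attributed to ICI if a qualifying drug was
#' administered within the preceding 3 months (91 days) and to radiotherapy
#' if a qualifying course started within the preceding 12 months (365
#' days).  Both intervals are half-open, `[diagnosis - window, diagnosis)`:
#' treatment strictly before the diagnosis date.
#'
#' @param ici_days ICI look-back in days.
#' @param rt_days Radiotherapy look-back in days.
#' @return Object of class `attribution_windows`.
#' @export
attribution_windows <- function(ici_days = 91L, rt_days = 365L) {
  stopifnot(ici_days > 0, rt_days > 0)
  structure(list(ici_days = as.integer(ici_days),
                 rt_days = as.integer(rt_days)),
            class = "attribution_windows")
}

#' Attribute pneumonitis episodes to ICI and/or radiotherapy
#'
#' For each candidate episode, checks whether any listed ICI administration
#' falls in `[diagnosis - ici_days, diagnosis)` and whether any
#' radiotherapy course to a listed site has its first fraction in
#' `[diagnosis - rt_days, diagnosis)`, and labels the episode `"ICI"`,
#' `"RT"`, `"both"` or `"none"` accordingly.  The diagnosis date is the
#' symptom-onset date when a `diagnosis_date` column is present on
#' `candidates`, otherwise the index scan date.
#'
#' @param candidates Tibble of index reports with `patient_id` and
#'   `scan_date` (and optionally `diagnosis_date`).
#' @param ici_events,rt_events Treatment streams.
#' @param config A [term_config()] supplying the qualifying drug and site
#'   lists.
#' @param windows An [attribution_windows()].
#' @return `candidates` with columns `diagnosis_date` and `aetiology`.
#' @examples
#' cand <- tibble::tibble(patient_id = "P1",
#'                        scan_date = as.Date("2019-06-01"))
#' ici <- tibble::tibble(patient_id = "P1", drug = "Nivolumab",
#'                       admin_date = as.Date("2019-05-02"))
#' rt <- tibble::tibble(patient_id = character(0), site = character(0),
#'                      first_fraction_date = as.Date(character(0)))
#' attribute_aetiology(cand, ici, rt)$aetiology  # "ICI"
#' @export
attribute_aetiology <- function(candidates, ici_events, rt_events,
                                config = term_config(),
                                windows = attribution_windows()) {
  if (!"diagnosis_date" %in% names(candidates)) {
    candidates$diagnosis_date <- candidates$scan_date
  }
  stopifnot(!any(is.na(candidates$diagnosis_date)))
  ici_ok <- ici_events[tolower(ici_events$drug) %in% config$ici_drugs, ]
  rt_ok <- rt_events[tolower(rt_events$site) %in% config$rt_sites, ]
  ici_by_pat <- split(as.numeric(ici_ok$admin_date), ici_ok$patient_id)
  rt_by_pat <- split(as.numeric(rt_ok$first_fraction_date), rt_ok$patient_id)
  d <- as.numeric(candidates$diagnosis_date)
  in_window <- function(events, at, win) {
    !is.null(events) && any(events >= at - win & events < at)
  }
  ici_hit <- vapply(seq_len(nrow(candidates)), function(i) {
    in_window(ici_by_pat[[candidates$patient_id[i]]], d[i], windows$ici_days)
  }, logical(1))
  rt_hit <- vapply(seq_len(nrow(candidates)), function(i) {
    in_window(rt_by_pat[[candidates$patient_id[i]]], d[i], windows$rt_days)
  }, logical(1))
  candidates$aetiology <- ifelse(ici_hit & rt_hit, "both",
                                 ifelse(ici_hit, "ICI",
                                        ifelse(rt_hit, "RT", "none")))
  candidates
}

#' Build pneumonitis case records from attributed candidates
#'
#' Drops candidates attributable to neither treatment (returned separately,
#' mirroring a manual exclusion step), derives CTCAE severity flags from
#' the clinical event stream (events on or after the diagnosis date), and
#' assigns the grade via [assign_grade()].
#'
#' @param attributed Output of [attribute_aetiology()].
#' @param clinical Clinical event stream.
#' @return List with `cases` (patient_id, diagnosis_date, aetiology, the
#'   four severity flags, superadded-infection flag, grade) and `excluded`
#'   (the aetiology-`none` candidates).
#' @export
build_cases <- function(attributed, clinical) {
  excluded <- attributed[attributed$aetiology == "none", ]
  kept <- attributed[attributed$aetiology != "none", ]
  ev_by_pat <- split(clinical[, c("event_type", "event_date")],
                     clinical$patient_id)
  flag <- function(i, type) {
    ev <- ev_by_pat[[kept$patient_id[i]]]
    !is.null(ev) && any(ev$event_type == type &
                          ev$event_date >= kept$diagnosis_date[i])
  }
  n <- nrow(kept)
  get_flags <- function(type) {
    vapply(seq_len(n), flag, logical(1), type = type)
  }
  kept$symptomatic <- get_flags("symptoms")
  kept$oxygen_or_admission <- get_flags("oxygen_or_admission")
  kept$life_threatening <- get_flags("intubation")
  kept$death <- get_flags("death")
  kept$superadded_infection <- get_flags("infection")
  kept$grade <- assign_grade(kept$symptomatic, kept$oxygen_or_admission,
                             kept$life_threatening, kept$death)
  list(cases = kept, excluded = excluded)
}

#' Treatment time lost between hold and re-challenge
#'
#' @param hold_date Date the drug was held (last administration before the
#'   episode).
#' @param restart_date Date of the first administration after the episode;
#'   `NA` if never re-challenged.
#' @return Days between the two dates, or `NA` when never re-challenged.
#'   A restart before the hold is a data error.
#' @examples
#' lost_treatment_time(as.Date("2020-01-01"), as.Date("2020-03-14")) # 73
#' @export
lost_treatment_time <- function(hold_date, restart_date) {
  out <- as.numeric(restart_date - hold_date)
  if (any(out < 0, na.rm = TRUE)) {
    stop("data error: re-challenge date precedes hold date", call. = FALSE)
  }
  out
}

#' Per-case lost treatment time from the administration stream
#'
#' For each ICI-attributed case, the hold date is the last administration
#' strictly before the diagnosis and the restart the first administration
#' strictly after it; cases never re-challenged get `NA`.
#'
#' @param cases Case tibble with `patient_id`, `diagnosis_date`,
#'   `aetiology`.
#' @param ici_events ICI administration stream.
#' @return Numeric vector of lost days aligned with `cases` rows (`NA` for
#'   non-ICI aetiology or no re-challenge).
#' @export
rechallenge_gaps <- function(cases, ici_events) {
  by_pat <- split(as.numeric(ici_events$admin_date), ici_events$patient_id)
  vapply(seq_len(nrow(cases)), function(i) {
    if (!cases$aetiology[i] %in% c("ICI", "both")) return(NA_real_)
    adm <- by_pat[[cases$patient_id[i]]]
    d <- as.numeric(cases$diagnosis_date[i])
    pre <- adm[adm < d]
    post <- adm[adm > d]
    if (length(pre) == 0 || length(post) == 0) return(NA_real_)
    lost_treatment_time(max(pre), min(post))
  }, numeric(1))
}
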