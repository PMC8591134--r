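# Two-stage keyword cascade over CT report text, structured treatment
# filters, and temporal episode deduplication.

#' Term and filter configuration for cohort identification
#'
#' Holds the keyword cascade vocabulary and structured-filter lists.
#' Matching downstream is case-insensitive, punctuation-tolerant substring
#' search over whitespace-normalised text (the behaviour of a SQL `LIKE`
#' scan): there is no stemming and no word-boundary enforcement, so
#' "pneumonia" also matches inside "pneumonias", while "pneumonitis" does
#' not match "pneumonia".
#'
#' @param stage1_terms Phrases that flag a report in either the request or
#'   the body section.
#' @param stage2_terms Phrases that must additionally appear in the report
#'   section given by `stage2_scope` for the report to survive filtering.
#' @param ici_drugs Qualifying immune-checkpoint-inhibitor drugs.
#' @param rt_sites Qualifying radiotherapy sites.
#' @param dedup_window_days Episode deduplication window; scans within this
#'   many days of the last kept scan belong to the same episode (183 days,
#'   i.e. 6 months).
#' @param stage2_scope `"body"` (default) restricts stage-2 phrases to the
#'   radiologist's findings, excluding the request section where clinicians
#'   typically query "?pneumonitis"; `"all"` scans both sections.
#' @return Object of class `term_config` with lower-cased phrase lists.
#' @export
term_config <- function(stage1_terms = c("pneumonitis", "pulmonary toxicity",
                                         "lung toxicity", "lung injury",
                                         "interstitial lung disease",
                                         "pneumonia"),
                        stage2_terms = c("ground glass", "treatment", "drug",
                                         "diffuse", "infiltrates",
                                         "radiotherapy", "radiation"),
                        ici_drugs = c("Atezolizumab", "Avelumab",
                                      "Durvalumab", "Ipilimumab",
                                      "Nivolumab", "Pembrolizumab"),
                        rt_sites = c("thorax", "upper abdomen", "neck",
                                     "vertebrae", "breast", "chest wall"),
                        dedup_window_days = 183L,
                        stage2_scope = c("body", "all")) {
  stopifnot(length(stage1_terms) > 0, length(stage2_terms) > 0,
            length(ici_drugs) > 0, length(rt_sites) > 0,
            dedup_window_days > 0)
  structure(list(stage1_terms = tolower(stage1_terms),
                 stage2_terms = tolower(stage2_terms),
                 ici_drugs = tolower(ici_drugs),
                 rt_sites = tolower(rt_sites),
                 dedup_window_days = as.integer(dedup_window_days),
                 stage2_scope = match.arg(stage2_scope)),
            class = "term_config")
}

#' Stage 1: flag reports containing any key term
#'
#' A report is flagged iff at least one stage-1 phrase occurs (normalised
#' substring match) in its request or body text.  Records without a scan
#' date cannot be placed on the episode timeline and are rejected with a
#' warning.
#'
#' @param reports Tibble with `report_id`, `patient_id`, `scan_date`,
#'   `request_text`, `body_text`.
#' @param config A [term_config()].
#' @return The flagged subset of `reports` with extra columns
#'   `stage1_terms` (comma-separated matches) and `match_section`
#'   (`"request"`, `"body"` or `"both"`).
#' @export
flag_stage1 <- function(reports, config = term_config()) {
  stopifnot(all(c("report_id", "patient_id", "scan_date", "request_text",
                  "body_text") %in% names(reports)))
  bad <- is.na(reports$scan_date)
  if (any(bad)) {
    warning(sum(bad), " report(s) rejected: missing scan date", call. = FALSE)
    reports <- reports[!bad, ]
  }
  terms <- normalise_text(config$stage1_terms)
  hit_req <- phrase_hits(normalise_text(reports$request_text), terms)
  hit_body <- phrase_hits(normalise_text(reports$body_text), terms)
  any_hit <- rowSums(hit_req | hit_body) > 0
  out <- reports[any_hit, ]
  out$stage1_terms <- collapse_hits((hit_req | hit_body)[any_hit, , drop = FALSE])
  section <- ifelse(rowSums(hit_req) > 0 & rowSums(hit_body) > 0, "both",
                    ifelse(rowSums(hit_body) > 0, "body", "request"))
  out$match_section <- section[any_hit]
  out
}

#' Stage 2: retain reports whose findings contain a filter term
#'
#' Keeps a flagged report iff at least one stage-2 phrase occurs in the
#' report body (radiologist's findings).  With
#' `config$stage2_scope = "all"` the request section is scanned too.
#' Output is always a subset of the input.
#'
#' @param flagged Output of [flag_stage1()].
#' @param config A [term_config()].
#' @return Subset of `flagged` with extra column `stage2_terms`.
#' @export
filter_stage2 <- function(flagged, config = term_config()) {
  terms <- normalise_text(config$stage2_terms)
  text <- normalise_text(flagged$body_text)
  if (config$stage2_scope == "all") {
    text <- paste(normalise_text(flagged$request_text), text)
  }
  hits <- phrase_hits(text, terms)
  keep <- rowSums(hits) > 0
  out <- flagged[keep, ]
  out$stage2_terms <- collapse_hits(hits[keep, , drop = FALSE])
  out
}

#' Filter flagged reports by prior qualifying treatment
#'
#' Retains a report iff its patient has at least one administration of a
#' listed ICI drug, or at least one radiotherapy course to a listed site,
#' strictly before the scan date.  Treatment rows with unlisted drugs or
#' sites never qualify; their count is reported via `message()`.
#'
#' @param flagged Flagged-report tibble (any stage).
#' @param ici_events Tibble with `patient_id`, `drug`, `admin_date`.
#' @param rt_events Tibble with `patient_id`, `site`, `first_fraction_date`.
#' @param config A [term_config()].
#' @return Subset of `flagged`.
#' @export
filter_by_treatment <- function(flagged, ici_events, rt_events,
                                config = term_config()) {
  unknown_drug <- !(tolower(ici_events$drug) %in% config$ici_drugs)
  unknown_site <- !(tolower(rt_events$site) %in% config$rt_sites)
  if (any(unknown_drug) || any(unknown_site)) {
    message("ignoring ", sum(unknown_drug), " administration(s) of unlisted ",
            "drugs and ", sum(unknown_site), " course(s) to unlisted sites")
  }
  ici_ok <- ici_events[!unknown_drug, ]
  rt_ok <- rt_events[!unknown_site, ]
  # any qualifying event strictly before the scan <=> earliest one is
  first_of <- function(dates, ids) {
    if (length(dates) == 0) return(stats::setNames(numeric(0), character(0)))
    tapply(as.numeric(dates), ids, min)
  }
  first_ici <- first_of(ici_ok$admin_date, ici_ok$patient_id)
  first_rt <- first_of(rt_ok$first_fraction_date, rt_ok$patient_id)
  scan <- as.numeric(flagged$scan_date)
  keep <- (!is.na(first_ici[flagged$patient_id]) &
             first_ici[flagged$patient_id] < scan) |
    (!is.na(first_rt[flagged$patient_id]) &
       first_rt[flagged$patient_id] < scan)
  keep[is.na(keep)] <- FALSE
  flagged[keep, ]
}

#' Collapse flagged reports into distinct pneumonitis episodes
#'
#' Greedy earliest-first interval suppression per patient: the earliest
#' report is kept; every subsequent report within `window_days` of the last
#' *kept* report is suppressed as the same episode; a later report beyond
#' the window opens a new episode.  The operation is deterministic and
#' idempotent.  Same-day duplicates are resolved by a stable secondary sort
#' on `report_id` (reported via `message()`).
#'
#' @param flagged Flagged-report tibble with `patient_id`, `scan_date`,
#'   `report_id`.
#' @param window_days Suppression window in days (default 183, 6 months).
#' @return Subset of `flagged` (the index report of each episode) with an
#'   `episode` number per patient.
#' @export
deduplicate_episodes <- function(flagged, window_days = 183L) {
  stopifnot(window_days > 0)
  if (nrow(flagged) == 0) {
    flagged$episode <- integer(0)
    return(flagged)
  }
  ord <- order(flagged$patient_id, flagged$scan_date, flagged$report_id)
  x <- flagged[ord, ]
  dup_day <- duplicated(x[, c("patient_id", "scan_date")])
  if (any(dup_day)) {
    message(sum(dup_day), " same-day duplicate report(s) resolved by ",
            "report id order")
  }
  keep <- logical(nrow(x))
  episode <- integer(nrow(x))
  last_kept <- -Inf
  last_pid <- ""
  ep <- 0L
  for (i in seq_len(nrow(x))) {
    if (x$patient_id[i] != last_pid) {
      last_pid <- x$patient_id[i]
      last_kept <- -Inf
      ep <- 0L
    }
    d <- as.numeric(x$scan_date[i])
    if (d - last_kept > window_days) {
      keep[i] <- TRUE
      last_kept <- d
      ep <- ep + 1L
    }
    episode[i] <- ep
  }
  out <- x[keep, ]
  out$episode <- episode[keep]
  out
}

#' Run the full identification cascade
#'
#' Applies [flag_stage1()], [filter_stage2()], [filter_by_treatment()], an
#' optional manual-validation exclusion list, and
#' [deduplicate_episodes()], recording the funnel count after each stage.
#'
#' @param reports Report stream.
#' @param ici_events,rt_events Treatment streams.
#' @param config A [term_config()].
#' @param exclusions Optional character vector of `report_id`s removed by
#'   manual validation before deduplication.
#' @return List with `index_reports` (one row per episode) and `funnel`
#'   (named integer vector: reports, stage1, stage2, treatment, validated,
#'   episodes).
#' @export
identify_cases <- function(reports, ici_events, rt_events,
                           config = term_config(), exclusions = NULL) {
  s1 <- flag_stage1(reports, config)
  s2 <- filter_stage2(s1, config)
  tr <- filter_by_treatment(s2, ici_events, rt_events, config)
  val <- tr[!(tr$report_id %in% exclusions), ]
  idx <- deduplicate_episodes(val, config$dedup_window_days)
  funnel <- c(reports = nrow(reports), stage1 = nrow(s1), stage2 = nrow(s2),
              treatment = nrow(tr), validated = nrow(val),
              episodes = nrow(idx))
  list(index_reports = idx, funnel = funnel)
}
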