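# Small fixture builders shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_reports <- function(body, request = "", dates = NULL, pid = NULL) {
  n <- length(body)
  tibble::tibble(
    report_id = sprintf("R%03d", seq_len(n)),
    patient_id = pid %||% sprintf("P%03d", seq_len(n)),
    scan_date = dates %||% rep(as.Date("2018-01-01"), n),
    request_text = rep_len(request, n),
    body_text = body)
}

mk_events <- function(pid, type, dates, value = NA_real_) {
  tibble::tibble(patient_id = pid, event_type = type,
                 event_date = dates,
                 value = rep_len(value, length(pid)))
}
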