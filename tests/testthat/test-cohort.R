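# Keyword cascade, treatment filters and episode deduplication.

test_that("stage 1 flags key terms in either section, case-insensitively", {
  r <- mk_reports(c("features in keeping with pneumonitis",
                    "",
                    "Interstitial Lung Disease pattern.",
                    "stable appearances"),
                  request = "")
  out <- flag_stage1(r)
  expect_identical(out$report_id, c("R001", "R003"))
  expect_identical(out$stage1_terms[1], "pneumonitis")
  # request-section terms flag too, with the section recorded
  r2 <- mk_reports("clear lungs", request = "?pneumonitis")
  out2 <- flag_stage1(r2)
  expect_identical(out2$match_section, "request")
  # punctuation-tolerant, no word boundaries: "pneumonias" matches "pneumonia"
  expect_equal(nrow(flag_stage1(mk_reports("multifocal pneumonias"))), 1)
  expect_equal(nrow(flag_stage1(mk_reports(""))), 0)
})

test_that("reports without a scan date are rejected with a warning", {
  r <- mk_reports(c("pneumonitis", "pneumonitis"),
                  dates = as.Date(c("2018-01-01", NA)))
  expect_warning(out <- flag_stage1(r), "missing scan date")
  expect_identical(out$report_id, "R001")
})

test_that("stage 2 evaluates filter terms on the body only", {
  r <- mk_reports(c("unremarkable", "diffuse ground glass"),
                  request = "?pneumonitis")
  s2 <- filter_stage2(flag_stage1(r))
  expect_identical(s2$report_id, "R002")
  expect_identical(s2$stage2_terms, "ground glass,diffuse")
  # widening the scope to both sections is configurable
  cfg <- term_config(stage2_scope = "all")
  r3 <- mk_reports("unremarkable", request = "?drug pneumonitis")
  expect_equal(nrow(filter_stage2(flag_stage1(r3, cfg), cfg)), 1)
})

test_that("treatment filter requires a qualifying exposure before the scan", {
  r <- mk_reports(rep("pneumonitis with ground glass", 4),
                  dates = rep(as.Date("2019-06-01"), 4),
                  pid = c("A", "B", "C", "D"))
  ici <- tibble::tibble(
    patient_id = c("A", "C", "D"),
    drug = c("Pembrolizumab", "Bevacizumab", "Pembrolizumab"),
    admin_date = as.Date(c("2019-04-01", "2019-04-01", "2019-06-01")))
  rt <- tibble::tibble(patient_id = "B", site = "brain",
                       first_fraction_date = as.Date("2019-01-01"))
  expect_message(out <- filter_by_treatment(r, ici, rt), "unlisted")
  # A: listed drug before scan; B: unlisted site; C: unlisted drug;
  # D: same-day administration is not strictly before
  expect_identical(out$patient_id, "A")
  # no treatment rows at all: removed
  empty_ici <- ici[0, ]
  empty_rt <- rt[0, ]
  expect_equal(nrow(filter_by_treatment(r, empty_ici, empty_rt)), 0)
})

test_that("cascade stages are monotone and term-monotone", {
  co <- generate_cohort(generator_config(n_patients = 400, seed = 14))
  cfg <- term_config()
  s1 <- suppressMessages(flag_stage1(co$reports, cfg))
  s2 <- filter_stage2(s1, cfg)
  tr <- suppressMessages(filter_by_treatment(s2, co$ici, co$rt, cfg))
  expect_true(all(s2$report_id %in% s1$report_id))
  expect_true(all(tr$report_id %in% s2$report_id))
  # adding a phrase never shrinks the flagged set
  cfg2 <- term_config(stage1_terms = c(cfg$stage1_terms, "nodule"))
  s1b <- flag_stage1(co$reports, cfg2)
  expect_true(all(s1$report_id %in% s1b$report_id))
})

test_that("episode deduplication keeps earliest-first greedy episodes", {
  d0 <- as.Date("2018-03-01")
  r <- mk_reports(rep("x", 3), pid = rep("P1", 3),
                  dates = d0 + c(0, 60, 200))
  out <- deduplicate_episodes(r, 183)
  expect_identical(as.numeric(out$scan_date - d0), c(0, 200))
  expect_identical(out$episode, c(1L, 2L))
  # single report unchanged; the operation is idempotent
  one <- deduplicate_episodes(r[1, ], 183)
  expect_identical(one$report_id, "R001")
  again <- deduplicate_episodes(out, 183)
  expect_identical(again$report_id, out$report_id)
})

test_that("same-day duplicates resolve by stable report-id order", {
  r <- mk_reports(rep("x", 2), pid = c("P1", "P1"),
                  dates = rep(as.Date("2018-01-01"), 2))
  expect_message(out <- deduplicate_episodes(r, 183), "same-day")
  expect_identical(out$report_id, "R001")
})

test_that("deduplication matches the interval-suppression oracle", {
  set.seed(70)
  for (k in 1:300) {
    n <- sample(1:12, 1)
    dates <- as.Date("2016-01-01") + sample(0:900, n, replace = TRUE)
    r <- mk_reports(rep("x", n), pid = rep("Q", n), dates = dates)
    w <- sample(c(30, 90, 183), 1)
    out <- suppressMessages(deduplicate_episodes(r, w))
    expect_identical(sort(out$scan_date), oracle_suppress(dates, w))
  }
})

test_that("cascade equals brute-force phrase scan on a random corpus", {
  reports <- random_corpus(200, seed = 81)
  cfg <- term_config()
  s1 <- flag_stage1(reports, cfg)
  expect_setequal(s1$report_id, oracle_stage1_ids(reports, cfg$stage1_terms))
  s2 <- filter_stage2(s1, cfg)
  expect_setequal(s2$report_id,
                  oracle_stage2_ids(reports, cfg$stage1_terms,
                                    cfg$stage2_terms))
})

test_that("distractor-free cohorts are recovered exactly; negated mentions
           cost precision but not recall", {
  cfg0 <- generator_config(n_patients = 700, distractor_rate = 0, seed = 17)
  co <- generate_cohort(cfg0)
  res <- suppressMessages(
    identify_cases(co$reports, co$ici, co$rt, term_config()))
  truth_keys <- paste(co$truth$patient_id[co$truth$case],
                      co$truth$diagnosis_date[co$truth$case])
  found_keys <- paste(res$index_reports$patient_id,
                      res$index_reports$scan_date)
  expect_setequal(found_keys, truth_keys)  # precision = recall = 1

  cfg1 <- generator_config(n_patients = 700, distractor_rate = 0.3,
                           seed = 17)
  co1 <- generate_cohort(cfg1)
  res1 <- suppressMessages(
    identify_cases(co1$reports, co1$ici, co1$rt, term_config()))
  tk <- paste(co1$truth$patient_id[co1$truth$case],
              co1$truth$diagnosis_date[co1$truth$case])
  fk <- paste(res1$index_reports$patient_id, res1$index_reports$scan_date)
  expect_true(all(tk %in% fk))       # recall stays 1
  expect_gt(length(fk), length(tk))  # negated/infective mentions slip through
})
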