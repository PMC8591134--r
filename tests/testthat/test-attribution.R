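# Aetiology attribution windows and lost-treatment-time arithmetic.

mk_cand <- function(pid, date) {
  tibble::tibble(patient_id = pid, scan_date = as.Date(date),
                 report_id = paste0("R", seq_along(pid)))
}
empty_ici <- tibble::tibble(patient_id = character(0), drug = character(0),
                            admin_date = as.Date(character(0)))
empty_rt <- tibble::tibble(patient_id = character(0), site = character(0),
                           first_fraction_date = as.Date(character(0)))

test_that("window rules label ICI, RT, both and none correctly", {
  d <- as.Date("2019-06-01")
  cand <- mk_cand(rep("P1", 1), d)
  ici30 <- tibble::tibble(patient_id = "P1", drug = "Nivolumab",
                          admin_date = d - 30)
  expect_identical(attribute_aetiology(cand, ici30, empty_rt)$aetiology,
                   "ICI")
  # ICI 120 d before is outside the 3-month window; RT 100 d inside 12 months
  ici120 <- tibble::tibble(patient_id = "P1", drug = "Nivolumab",
                           admin_date = d - 120)
  rt100 <- tibble::tibble(patient_id = "P1", site = "thorax",
                          first_fraction_date = d - 100)
  expect_identical(attribute_aetiology(cand, ici120, rt100)$aetiology, "RT")
  expect_identical(
    attribute_aetiology(cand, ici30, rt100)$aetiology, "both")
  expect_identical(
    attribute_aetiology(cand, ici120, empty_rt)$aetiology, "none")
  # boundary: exactly window days before is inside; same day is not
  ici91 <- tibble::tibble(patient_id = "P1", drug = "Nivolumab",
                          admin_date = d - 91)
  expect_identical(attribute_aetiology(cand, ici91, empty_rt)$aetiology,
                   "ICI")
  ici0 <- tibble::tibble(patient_id = "P1", drug = "Nivolumab",
                         admin_date = d)
  expect_identical(attribute_aetiology(cand, ici0, empty_rt)$aetiology,
                   "none")
})

test_that("a symptom-onset diagnosis date takes precedence over scan date", {
  d <- as.Date("2019-06-01")
  cand <- mk_cand("P1", d)
  cand$diagnosis_date <- d - 40  # symptoms began before the scan
  ici <- tibble::tibble(patient_id = "P1", drug = "Pembrolizumab",
                        admin_date = d - 120)  # 80 d before symptom onset
  expect_identical(attribute_aetiology(cand, ici, empty_rt)$aetiology, "ICI")
})

test_that("attribution matches a brute-force window check on random events", {
  set.seed(55)
  win <- attribution_windows()
  for (k in 1:100) {
    d <- as.Date("2018-01-01") + sample(0:900, 1)
    cand <- mk_cand("Z", d)
    ici <- tibble::tibble(
      patient_id = "Z", drug = "Durvalumab",
      admin_date = d + sample(-400:100, sample(0:5, 1), replace = TRUE))
    rt <- tibble::tibble(
      patient_id = "Z", site = "breast",
      first_fraction_date = d + sample(-700:50, sample(0:3, 1),
                                       replace = TRUE))
    got <- attribute_aetiology(cand, ici, rt, windows = win)$aetiology
    ici_hit <- any(ici$admin_date >= d - win$ici_days & ici$admin_date < d)
    rt_hit <- any(rt$first_fraction_date >= d - win$rt_days &
                    rt$first_fraction_date < d)
    want <- if (ici_hit && rt_hit) "both" else if (ici_hit) "ICI" else
      if (rt_hit) "RT" else "none"
    expect_identical(got, want)
  }
})

test_that("shrinking a window never adds that aetiology", {
  set.seed(56)
  d <- as.Date("2019-01-01")
  cand <- mk_cand(sprintf("P%d", 1:40), rep(d, 40))
  ici <- tibble::tibble(
    patient_id = sample(cand$patient_id, 80, replace = TRUE),
    drug = "Nivolumab",
    admin_date = d - sample(1:400, 80, replace = TRUE))
  wide <- attribute_aetiology(cand, ici, empty_rt,
                              windows = attribution_windows(ici_days = 91))
  narrow <- attribute_aetiology(cand, ici, empty_rt,
                                windows = attribution_windows(ici_days = 30))
  gained <- narrow$aetiology == "ICI" & wide$aetiology != "ICI"
  expect_false(any(gained))
})

test_that("attributed aetiology and grade are diagonal against ground truth", {
  co <- generate_cohort(generator_config(n_patients = 900,
                                         distractor_rate = 0, seed = 23))
  res <- suppressMessages(run_pipeline(co))
  m <- merge(res$cases[, c("patient_id", "aetiology", "grade")],
             co$truth[co$truth$case,
                      c("patient_id", "aetiology", "grade")],
             by = "patient_id")
  expect_equal(nrow(m), sum(co$truth$case))
  expect_identical(m$aetiology.x, m$aetiology.y)
  expect_identical(as.integer(m$grade.x), as.integer(m$grade.y))
})

test_that("lost treatment time is plain date arithmetic with guards", {
  expect_equal(lost_treatment_time(as.Date("2020-01-01"),
                                   as.Date("2020-03-14")), 73)
  expect_true(is.na(lost_treatment_time(as.Date("2020-01-01"),
                                        as.Date(NA))))
  expect_error(lost_treatment_time(as.Date("2020-01-01"),
                                   as.Date("2019-12-31")), "data error")
})

test_that("per-case gaps come from the administration stream", {
  d <- as.Date("2019-06-01")
  cases <- tibble::tibble(patient_id = c("A", "B"),
                          diagnosis_date = c(d, d),
                          aetiology = c("ICI", "ICI"))
  ici <- tibble::tibble(
    patient_id = c("A", "A", "A", "B"),
    drug = "Nivolumab",
    admin_date = c(d - 40, d - 10, d + 63, d - 5))  # B never re-challenged
  expect_equal(rechallenge_gaps(cases, ici), c(73, NA))
})
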