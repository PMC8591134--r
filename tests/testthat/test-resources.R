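# 16-week resource profiles and severity-strata comparison.

mk_case <- function(pid = "P1", date = "2019-01-01") {
  tibble::tibble(patient_id = pid, diagnosis_date = as.Date(date))
}

test_that("window counting is half-open at 112 days and includes day 0", {
  d <- as.Date("2019-01-01")
  ev <- mk_events(rep("P1", 3), "clinic_visit", d + c(7, 50, 120))
  prof <- extract_profiles(mk_case(), ev)
  expect_equal(prof$clinic_visits, 2)  # day 120 falls outside 16 weeks
  edge <- mk_events(rep("P1", 3), "clinic_visit", d + c(0, 111, 112))
  expect_equal(extract_profiles(mk_case(), edge)$clinic_visits, 2)
  # events before diagnosis are ignored
  pre <- mk_events("P1", "clinic_visit", d - 5)
  expect_equal(extract_profiles(mk_case(), pre)$clinic_visits, 0)
})

test_that("a case with no events yields an all-zero profile", {
  prof <- extract_profiles(mk_case(), mk_events(character(0), character(0),
                                                as.Date(character(0))))
  expect_equal(prof$clinic_visits, 0)
  expect_equal(prof$hospital_nights, 0)
  expect_false(prof$referral)
  expect_true(is.na(prof$days_to_review))
})

test_that("admissions starting in the window count their full duration;
           work-up flags have no window cut-off", {
  d <- as.Date("2019-01-01")
  ev <- rbind(mk_events("P1", "admission", d + 100, value = 30),
              mk_events("P1", "admission", d + 113, value = 7),
              mk_events("P1", "ccu_admission", d + 10, value = 6),
              mk_events("P1", "resp_review", d + 150),
              mk_events("P1", "bal", d + 35))
  prof <- extract_profiles(mk_case(), ev)
  expect_equal(prof$hospital_nights, 30)  # second stay starts after 16 wks
  expect_equal(prof$ccu_nights, 6)
  expect_true(prof$referral)
  expect_equal(prof$days_to_review, 150)
  expect_true(prof$bal)
  expect_equal(prof$days_to_bal, 35)
  expect_false(prof$pft)
})

test_that("window counts match a brute-force scan on random event streams", {
  set.seed(61)
  for (k in 1:50) {
    d <- as.Date("2018-01-01") + sample(0:500, 1)
    n <- sample(0:20, 1)
    types <- sample(c("clinic_visit", "ct_thorax", "mdt"), n, replace = TRUE)
    dates <- d + sample(-30:200, max(n, 1), replace = TRUE)[seq_len(n)]
    ev <- mk_events(rep("P1", n), types, dates)
    prof <- extract_profiles(mk_case(date = as.character(d)), ev)
    for (tp in c(clinic_visits = "clinic_visit", ct_scans = "ct_thorax",
                 mdt_discussions = "mdt")) {
      want <- sum(types == tp & dates >= d & dates < d + 112)
      col <- names(which(c(clinic_visits = "clinic_visit",
                           ct_scans = "ct_thorax",
                           mdt_discussions = "mdt") == tp))
      expect_equal(prof[[col]], want)
    }
  }
})

test_that("counting is translation-invariant and additive under doubling", {
  d <- as.Date("2019-01-01")
  ev <- mk_events(rep("P1", 4), "clinic_visit", d + c(1, 30, 60, 90))
  base <- extract_profiles(mk_case(), ev)$clinic_visits
  shift <- 500
  ev2 <- mk_events(rep("P1", 4), "clinic_visit", d + shift + c(1, 30, 60, 90))
  shifted <- extract_profiles(mk_case(date = as.character(d + shift)),
                              ev2)$clinic_visits
  expect_equal(shifted, base)
  doubled <- extract_profiles(mk_case(), rbind(ev, ev))$clinic_visits
  expect_equal(doubled, 2 * base)
})

test_that("Welch comparison matches the closed-form statistic", {
  prof <- tibble::tibble(clinic_visits = c(1, 2, 3, 3, 4, 5))
  grades <- c(1, 1, 1, 2, 3, 4)
  got <- compare_strata(prof, grades)
  want <- oracle_welch(c(3, 4, 5), c(1, 2, 3))
  expect_equal(got$diff, 2)
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p)
  ci_width <- stats::qt(0.975, want$df) * sqrt(2 / 3)  # equal variances 1
  expect_equal(c(got$ci_lower, got$ci_upper), 2 + c(-1, 1) * ci_width)
})

test_that("identical strata give difference zero and p-value one", {
  prof <- tibble::tibble(clinic_visits = c(1, 2, 3, 1, 2, 3))
  got <- compare_strata(prof, c(1, 1, 1, 2, 2, 3))
  expect_equal(got$diff, 0)
  expect_equal(got$p_value, 1)
})

test_that("grade 5 cases are excluded and small strata are rejected", {
  prof <- tibble::tibble(clinic_visits = c(1, 2, 10, 10, 3, 4))
  grades <- c(1, 1, 5, 5, 2, 2)
  got <- compare_strata(prof, grades)
  expect_equal(got$n_grade24, 2)  # the two grade-5 outliers never enter
  expect_equal(got$mean_grade24, 3.5)
  expect_error(compare_strata(tibble::tibble(clinic_visits = c(1, 2)),
                              c(1, 2)), "at least two")
})

test_that("Welch equals the pooled t-test under equal variances and sizes", {
  x <- c(1, 2, 3, 4)
  y <- c(5, 6, 7, 8)
  w <- stats::t.test(x, y, var.equal = FALSE)
  p <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(unname(w$statistic), unname(p$statistic))
  expect_equal(unname(w$parameter), unname(p$parameter))
})

test_that("the 95% CI covers a configured group difference of 2.21 in at
           least 93% of replicates", {
  set.seed(64)
  hit <- 0
  for (r in 1:200) {
    g1 <- stats::rpois(60, 4.40)
    g24 <- stats::rpois(40, 6.61)
    prof <- tibble::tibble(clinic_visits = c(g1, g24))
    got <- compare_strata(prof, c(rep(1, 60), rep(2, 40)))
    if (got$ci_lower <= 2.21 && 2.21 <= got$ci_upper) hit <- hit + 1
  }
  expect_gte(hit / 200, 0.93)
})
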