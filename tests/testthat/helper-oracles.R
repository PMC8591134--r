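# Independent brute-force oracles, deliberately written without reusing the
# package's internals: naive per-(record, phrase) scans, direct interval
# suppression, the pairwise-disagreement form of Krippendorff's alpha, and
# the closed-form Welch statistic.

# naive phrase containment: loop over every (text, phrase) pair
oracle_norm <- function(x) {
  x[is.na(x)] <- ""
  trimws(gsub("[^a-z0-9]+", " ", tolower(x)))
}

oracle_contains <- function(text, phrase) {
  grepl(oracle_norm(phrase), oracle_norm(text), fixed = TRUE)
}

oracle_stage1_ids <- function(reports, stage1) {
  keep <- vapply(seq_len(nrow(reports)), function(i) {
    any(vapply(stage1, function(tm) {
      oracle_contains(reports$request_text[i], tm) ||
        oracle_contains(reports$body_text[i], tm)
    }, logical(1)))
  }, logical(1))
  reports$report_id[keep & !is.na(reports$scan_date)]
}

oracle_stage2_ids <- function(reports, stage1, stage2) {
  ids1 <- oracle_stage1_ids(reports, stage1)
  keep <- vapply(seq_len(nrow(reports)), function(i) {
    reports$report_id[i] %in% ids1 &&
      any(vapply(stage2, function(tm) {
        oracle_contains(reports$body_text[i], tm)
      }, logical(1)))
  }, logical(1))
  reports$report_id[keep]
}

oracle_treatment_ids <- function(reports, ids, ici, rt, drugs, sites) {
  keep <- vapply(seq_len(nrow(reports)), function(i) {
    if (!reports$report_id[i] %in% ids) return(FALSE)
    p <- reports$patient_id[i]
    d <- reports$scan_date[i]
    had_ici <- any(ici$patient_id == p &
                     tolower(ici$drug) %in% tolower(drugs) &
                     ici$admin_date < d)
    had_rt <- any(rt$patient_id == p &
                    tolower(rt$site) %in% tolower(sites) &
                    rt$first_fraction_date < d)
    had_ici || had_rt
  }, logical(1))
  reports$report_id[keep]
}

# greedy earliest-first interval suppression on a sorted date vector
oracle_suppress <- function(dates, window) {
  dates <- sort(dates)
  kept <- as.Date(character(0))
  for (d in seq_along(dates)) {
    if (length(kept) == 0 ||
        as.numeric(dates[d] - kept[length(kept)]) > window) {
      kept <- c(kept, dates[d])
    }
  }
  kept
}

# Krippendorff's alpha straight from pairwise disagreements (no coincidence
# matrix): D_o averages within-item pair differences, D_e averages
# differences over every cross-item pair of pairable values.
oracle_alpha <- function(ratings, metric = "interval") {
  m <- as.matrix(ratings)
  m <- m[rowSums(!is.na(m)) >= 2, , drop = FALSE]
  vals_by_item <- lapply(seq_len(nrow(m)),
                         function(u) unname(m[u, !is.na(m[u, ])]))
  allv <- unlist(vals_by_item)
  n <- length(allv)

  if (metric == "ordinal") {
    lv <- sort(unique(allv))
    nk <- vapply(lv, function(v) sum(allv == v), numeric(1))
    dfun <- function(a, b) {
      if (a == b) return(0)
      ia <- which(lv == a); ib <- which(lv == b)
      rng <- min(ia, ib):max(ia, ib)
      (sum(nk[rng]) - (nk[ia] + nk[ib]) / 2)^2
    }
  } else if (metric == "nominal") {
    dfun <- function(a, b) as.numeric(a != b)
  } else {
    dfun <- function(a, b) (a - b)^2
  }

  d_obs <- 0
  for (vals in vals_by_item) {
    mu <- length(vals)
    s <- 0
    for (i in seq_len(mu)) {
      for (j in seq_len(mu)) if (i != j) s <- s + dfun(vals[i], vals[j])
    }
    d_obs <- d_obs + s / (mu - 1)
  }
  d_obs <- d_obs / n

  d_exp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (i != j) d_exp <- d_exp + dfun(allv[i], allv[j])
  }
  d_exp <- d_exp / (n * (n - 1))
  if (d_exp == 0) return(1)
  1 - d_obs / d_exp
}

# closed-form Welch statistic, dof and two-sided p
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# random report corpus mixing flag terms, filter terms and clean prose
random_corpus <- function(n, seed) {
  set.seed(seed)
  vocab <- c("pneumonitis", "pulmonary toxicity", "lung injury", "pneumonia",
             "interstitial lung disease", "ground glass", "treatment",
             "drug", "diffuse", "infiltrates", "radiotherapy", "radiation",
             "unremarkable", "clear lungs", "no change", "effusion",
             "nodule stable", "atelectasis", "?pneumonitis", "pneumonias")
  mk <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(vocab, sample(0:6, 1), replace = TRUE), collapse = ". ")
    }, character(1))
  }
  tibble::tibble(
    report_id = sprintf("X%04d", seq_len(n)),
    patient_id = sprintf("P%03d", sample(ceiling(n / 3), n, replace = TRUE)),
    scan_date = as.Date("2017-01-01") + sample(0:1400, n, replace = TRUE),
    request_text = mk(n),
    body_text = mk(n))
}

random_treatments <- function(patients, seed) {
  set.seed(seed)
  n_ici <- length(patients)
  ici <- tibble::tibble(
    patient_id = sample(patients, n_ici, replace = TRUE),
    drug = sample(c("Pembrolizumab", "Nivolumab", "Durvalumab",
                    "Bevacizumab", "Cisplatin"), n_ici, replace = TRUE),
    admin_date = as.Date("2016-06-01") + sample(0:1600, n_ici, replace = TRUE))
  rt <- tibble::tibble(
    patient_id = sample(patients, ceiling(n_ici / 2), replace = TRUE),
    site = sample(c("thorax", "breast", "brain", "pelvis", "neck"),
                  ceiling(n_ici / 2), replace = TRUE),
    dose_gy = 20, fractions = 5L,
    first_fraction_date = as.Date("2016-06-01") +
      sample(0:1600, ceiling(n_ici / 2), replace = TRUE))
  list(ici = ici, rt = rt)
}
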