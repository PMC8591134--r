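# CTCAE v5.0 severity grading from structured flags, and Krippendorff's
# alpha for inter-rater concordance.

#' Assign a CTCAE v5.0 pneumonitis grade from clinical flags
#'
#' Rule cascade, most severe first: death gives grade 5; else a
#' life-threatening episode (intubation) grade 4; else severe symptoms with
#' oxygen or hospital admission indicated grade 3; else any symptoms
#' requiring medical intervention grade 2; else grade 1 (asymptomatic,
#' radiological finding only).  Every flag combination maps to exactly one
#' grade and missing flags count as `FALSE`.
#'
#' @param symptomatic,oxygen_or_admission,life_threatening,death Logical
#'   vectors (recycled to a common length).
#' @return Integer vector of grades in 1..5.
#' @examples
#' assign_grade(symptomatic = TRUE, oxygen_or_admission = TRUE,
#'              life_threatening = FALSE, death = FALSE) # 3
#' @export
assign_grade <- function(symptomatic = FALSE, oxygen_or_admission = FALSE,
                         life_threatening = FALSE, death = FALSE) {
  n <- max(length(symptomatic), length(oxygen_or_admission),
           length(life_threatening), length(death))
  f <- function(x) {
    x <- rep_len(x, n)
    x[is.na(x)] <- FALSE
    x
  }
  symptomatic <- f(symptomatic); oxygen_or_admission <- f(oxygen_or_admission)
  life_threatening <- f(life_threatening); death <- f(death)
  ifelse(death, 5L,
         ifelse(life_threatening, 4L,
                ifelse(oxygen_or_admission, 3L,
                       ifelse(symptomatic, 2L, 1L))))
}

#' Krippendorff's alpha inter-rater reliability
#'
#' Chance-corrected agreement over a reliability matrix of items by raters,
#' computed as `1 - D_o / D_e` from the coincidence matrix of pairable
#' values.  Items rated by fewer than two raters are excluded.  Missing
#' ratings (`NA`) are allowed.
#'
#' Difference metrics: `"nominal"` (any disagreement counts 1),
#' `"interval"` (squared value difference, so adjacent grades disagree less
#' than distant ones; the default for ordered severity grades), and
#' `"ordinal"` (squared difference of cumulative coincidence ranks).
#'
#' When the expected disagreement is zero (every pairable value identical)
#' the statistic is 1 by convention, reported via `message()`.
#'
#' @param ratings Numeric matrix or data frame, rows = items, columns =
#'   raters; `NA` for missing.
#' @param metric Difference metric.
#' @return Alpha in `[-1, 1]`.
#' @examples
#' r <- cbind(r1 = c(1, 2, 3, 3, 2), r2 = c(1, 2, 3, 3, 2))
#' krippendorff_alpha(r)  # 1
#' @export
krippendorff_alpha <- function(ratings,
                               metric = c("interval", "nominal", "ordinal")) {
  metric <- match.arg(metric)
  m <- as.matrix(ratings)
  stopifnot(ncol(m) >= 2)
  pairable <- rowSums(!is.na(m)) >= 2
  m <- m[pairable, , drop = FALSE]
  if (nrow(m) == 0) stop("no item is rated by two or more raters")

  values <- sort(unique(stats::na.omit(as.vector(m))))
  v <- length(values)
  o <- matrix(0, v, v, dimnames = list(values, values))
  for (u in seq_len(nrow(m))) {
    obs <- stats::na.omit(m[u, ])
    mu <- length(obs)
    idx <- match(obs, values)
    for (i in seq_len(mu)) {
      for (j in seq_len(mu)) {
        if (i != j) o[idx[i], idx[j]] <- o[idx[i], idx[j]] + 1 / (mu - 1)
      }
    }
  }
  nc <- rowSums(o)
  ntot <- sum(nc)

  delta <- switch(metric,
    nominal = 1 - diag(v),
    interval = outer(values, values, function(a, b) (a - b)^2),
    ordinal = {
      d <- matrix(0, v, v)
      for (a in seq_len(v)) {
        for (b in seq_len(v)) {
          if (a != b) {
            rng <- min(a, b):max(a, b)
            d[a, b] <- (sum(nc[rng]) - (nc[a] + nc[b]) / 2)^2
          }
        }
      }
      d
    })

  d_obs <- sum(o * delta)
  d_exp <- sum(outer(nc, nc) * delta) / (ntot - 1)
  if (d_exp == 0) {
    message("expected disagreement is zero; alpha = 1 by convention")
    return(1)
  }
  1 - d_obs / d_exp
}
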