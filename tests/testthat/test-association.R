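make_scores <- function(values, biomarker = "RMS_Net_ECFT") {
  tibble::tibble(subject_id = sprintf("S%03d", seq_along(values)),
                 !!biomarker := values)
}

make_cohort <- function(n, age = NULL, diagnosis = "HV", ...) {
  if (is.null(age)) age <- runif(n, 20, 70)
  tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)),
                 age = age, diagnosis = diagnosis, ...)
}

test_that("subject scores average non-outlier trials per subject", {
  panel <- tibble::tibble(subject_id = rep(c("S001", "S002"), each = 2),
                          trial_id = rep(c("T1", "T2"), 2),
                          a = c(1, 3, 10, NA))
  flags <- tibble::tibble(subject_id = panel$subject_id,
                          trial_id = panel$trial_id,
                          a = c(FALSE, FALSE, TRUE, FALSE))
  sc <- subject_scores(panel, flags)
  expect_equal(sc$a, c(2, NA_real_))
})

test_that("an exactly linear outcome correlates perfectly", {
  set.seed(1)
  x <- rnorm(30)
  scores <- make_scores(x)
  cohort <- make_cohort(30, combiwise = 3 * x + 2)
  rep <- correlate_biomarkers(scores, cohort, "RMS_Net_ECFT", "combiwise")
  expect_equal(rep$r, 1, tolerance = 1e-12)
  expect_lt(rep$q_value, 1e-10)
  # sign equivariance
  rep2 <- correlate_biomarkers(make_scores(-x), cohort, "RMS_Net_ECFT",
                               "combiwise")
  expect_equal(rep2$r, -1, tolerance = 1e-12)
})

test_that("a designed correlation of 0.6 is estimated within 0.15", {
  for (s in 1:20) {
    set.seed(200 + s)
    x <- rnorm(150)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(150)
    rep <- correlate_biomarkers(make_scores(x), make_cohort(150, combiwise = y),
                                "RMS_Net_ECFT", "combiwise")
    expect_equal(rep$r, 0.6, tolerance = 0.15 / 0.6)
  }
})

test_that("permuted outcomes rarely reach significance", {
  fails <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    x <- rnorm(60)
    y <- sample(3 * x)
    rep <- correlate_biomarkers(make_scores(x), make_cohort(60, combiwise = y),
                                "RMS_Net_ECFT", "combiwise")
    if (!is.na(rep$q_value) && rep$q_value <= 0.05) fails <- fails + 1
  }
  expect_lte(fails, 2)
})

test_that("strata below the minimum size are dropped; sex is point-biserial", {
  set.seed(9)
  n <- 25
  x <- rnorm(n)
  cohort <- make_cohort(n, diagnosis = c(rep("HV", 20), rep("RIS", 5)),
                        sex = sample(c("M", "F"), n, replace = TRUE))
  rep <- correlate_biomarkers(make_scores(x), cohort, "RMS_Net_ECFT",
                              c("age", "sex"),
                              strata = c("HV", "RIS"))
  expect_setequal(unique(rep$stratum), "HV")
  expect_false(anyNA(rep$r))
  # constant outcome yields a missing cell
  cohort$height <- 170
  rep2 <- correlate_biomarkers(make_scores(x), cohort, "RMS_Net_ECFT",
                               "height")
  expect_true(is.na(rep2$r))
})

test_that("the prediction band matches the textbook interval from lm", {
  set.seed(12)
  n <- 60
  age <- runif(n, 20, 70)
  y <- 0.5 + 0.01 * age + rnorm(n, 0, 0.1)
  scores <- make_scores(y)
  cohort <- make_cohort(n, age = age)
  band <- fit_age_band(scores, cohort, "RMS_Net_ECFT")
  newage <- c(25, 45, 68)
  got <- predict_band(band, newage)
  fit <- lm(y ~ age)
  want <- predict(fit, newdata = data.frame(age = newage),
                  interval = "prediction", level = 0.95)
  expect_equal(got$fit, unname(want[, "fit"]), tolerance = 1e-10)
  expect_equal(got$lower, unname(want[, "lwr"]), tolerance = 1e-10)
  expect_equal(got$upper, unname(want[, "upr"]), tolerance = 1e-10)
  # band width is minimal at the mean reference age
  w <- function(a) {
    p <- predict_band(band, a)
    p$upper - p$lower
  }
  expect_lt(w(band$age_mean), w(band$age_mean + 10))
  expect_lt(w(band$age_mean), w(band$age_mean - 10))
})

test_that("a noiseless linear reference collapses the band onto the line", {
  age <- seq(20, 60, length.out = 20)
  y <- 1 + 0.02 * age
  band <- fit_age_band(make_scores(y), make_cohort(20, age = age),
                       "RMS_Net_ECFT")
  expect_equal(band$sigma, 0, tolerance = 1e-12)
  pb <- predict_band(band, 40)
  expect_equal(pb$lower, pb$upper, tolerance = 1e-10)
  expect_equal(band$slope, 0.02, tolerance = 1e-10)
})

test_that("the fitted slope lands within two standard errors of truth", {
  set.seed(31)
  n <- 200
  age <- runif(n, 20, 70)
  y <- 0.3 + 0.008 * age + rnorm(n, 0, 0.08)
  band <- fit_age_band(make_scores(y), make_cohort(n, age = age),
                       "RMS_Net_ECFT")
  se <- band$sigma / sqrt(band$sxx)
  expect_lt(abs(band$slope - 0.008), 2.5 * se)
})

test_that("abnormal calls behave like a one-sided 95 percent bound", {
  set.seed(21)
  n <- 400
  age <- runif(n, 20, 70)
  y <- 0.5 + 0.01 * age + rnorm(n, 0, 0.1)
  scores <- make_scores(y)
  cohort <- make_cohort(n, age = age)
  band <- fit_age_band(scores, cohort, "RMS_Net_ECFT")
  calls <- call_abnormal(band, scores, cohort)
  expect_lt(mean(calls$abnormal), 0.06)
  # a group shifted by 3 residual sd is nearly always abnormal
  shifted <- scores
  shifted$RMS_Net_ECFT <- shifted$RMS_Net_ECFT + 3 * band$sigma
  calls2 <- call_abnormal(band, shifted, cohort)
  expect_gt(mean(calls2$abnormal), 0.9)
  # extrapolation flag
  far <- make_cohort(1, age = band$age_range[2] + 20)
  far_scores <- make_scores(0.6)
  expect_true(call_abnormal(band, far_scores, far)$extrapolated)
})

test_that("abnormal fractions report per group, with NA for empty groups", {
  calls <- tibble::tibble(subject_id = sprintf("S%03d", 1:4),
                          diagnosis = c("HV", "HV", "MS-RR", "MS-RR"),
                          age = 40, value = 1, upper = 1.5,
                          abnormal = c(FALSE, TRUE, TRUE, TRUE),
                          extrapolated = FALSE)
  fr <- abnormal_fractions(calls, groups = c("HV", "MS-RR", "NIND"))
  expect_equal(fr$fraction_abnormal, c(0.5, 1, NA))
  expect_equal(fr$n, c(2, 2, 0))
})

test_that("group comparisons control type-I error and detect shifts", {
  # identical samples: maximal p under tie handling
  same <- rep(1:5, 2)
  g <- rep(c("A", "B"), each = 5)
  rep0 <- compare_groups(same, g)
  expect_gt(rep0$p_value, 0.9)

  # null rejection rate within the binomial-plausible window
  rej <- 0
  for (s in 1:200) {
    set.seed(400 + s)
    v <- rnorm(200)
    gg <- rep(c("A", "B"), each = 100)
    if (compare_groups(v, gg)$p_value <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.09)

  # a 2-sd shift at n = 30 per group is essentially always detected
  hits <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    v <- c(rnorm(30), rnorm(30, 2))
    gg <- rep(c("A", "B"), each = 30)
    if (compare_groups(v, gg)$q_value <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)

  # undersized groups are skipped; BH is applied across the pair family
  v <- c(rnorm(30), rnorm(30, 2), 1)
  gg <- c(rep(c("A", "B"), each = 30), "RIS")
  rep2 <- compare_groups(v, gg)
  expect_equal(nrow(rep2), 1)
  expect_error(compare_groups(rnorm(5), rep("A", 5)), "fewer than 2")
})
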