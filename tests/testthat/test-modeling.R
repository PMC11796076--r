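test_that("the cohort split is subject-level, sized and reproducible", {
  cohort <- tibble::tibble(subject_id = sprintf("S%03d", 1:150))
  s1 <- split_cohort(cohort, seed = 7)
  expect_equal(sum(s1$split == "train"), 120)
  expect_equal(sum(s1$split == "validation"), 30)
  s2 <- split_cohort(cohort, seed = 7)
  expect_identical(s1$split, s2$split)
  expect_false(identical(split_cohort(cohort, seed = 8)$split, s1$split))
  expect_error(split_cohort(cohort, train_fraction = 1.2), "in \\(0, 1\\)")
  expect_error(split_cohort(rbind(cohort, cohort[1, ])), "unique")
  # trials inherit the subject's label through a join, never their own draw
  trials <- tidyr::crossing(subject_id = cohort$subject_id,
                            trial_id = c("T1", "T2"))
  merged <- dplyr::left_join(trials, s1, by = "subject_id")
  per_subject <- tapply(merged$split, merged$subject_id,
                        function(x) length(unique(x)))
  expect_true(all(per_subject == 1))
})

test_that("ccc matches the mean-squared-deviation oracle and Lin's bound", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 1.9, 3.2, 3.8)
  expect_equal(ccc(x, y), ccc_oracle(x, y), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(25)
    b <- 0.7 * a + rnorm(25, 0, 0.5) + runif(1, -1, 1)
    expect_equal(ccc(a, b), ccc_oracle(a, b), tolerance = 1e-12)
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  expect_equal(ccc(x, x), 1)
  # a pure location shift keeps r = 1 but pulls CCC below 1
  expect_equal(cor(x, x + 2), 1)
  expect_lt(ccc(x, x + 2), 1)
})

test_that("a noiseless linear outcome is recovered almost exactly", {
  set.seed(11)
  n <- 120
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  beta <- c(2, -1, 0.5, 0, 0, 0)
  y <- drop(x %*% beta) + 3
  m <- tune_model(x, y, "ridge", seed = 1)
  expect_gt(m$cv_r2, 0.99)
  beta_raw <- m$beta / m$scale
  expect_lt(max(abs(beta_raw[1:3] - beta[1:3]) / abs(beta[1:3])), 0.05)
  v <- validate_model(m, x, y)
  expect_gt(v$r2, 0.999)
  expect_gt(v$ccc, 0.999)
})

test_that("a pure-noise outcome never shows optimistic CV performance", {
  for (s in 1:3) {
    set.seed(600 + s)
    x <- matrix(rnorm(100 * 8), 100, 8)
    y <- rnorm(100)
    m <- tune_model(x, y, "ridge", seed = s)
    expect_lte(m$cv_r2, 0.1)
  }
})

test_that("lasso keeps informative features and drops pure noise", {
  for (s in 1:3) {
    set.seed(700 + s)
    n <- 200
    xi <- matrix(rnorm(n * 5), n, 5,
                 dimnames = list(NULL, paste0("info", 1:5)))
    xn <- matrix(rnorm(n * 20), n, 20,
                 dimnames = list(NULL, paste0("noise", 1:20)))
    y <- drop(xi %*% rep(1, 5)) + rnorm(n, 0, sqrt(5) / 2)  # SNR 4
    m <- tune_model(cbind(xi, xn), y, "lasso", seed = s)
    kept <- names(m$beta)[abs(m$beta) > 1e-8]
    expect_gte(sum(grepl("^info", kept)), 4)
    expect_lte(sum(grepl("^noise", kept)), 5)
  }
})

test_that("elastic net searches the mixing grid and reports it", {
  set.seed(21)
  x <- matrix(rnorm(80 * 5), 80, 5)
  y <- drop(x %*% c(1, 1, 0, 0, 0)) + rnorm(80, 0, 0.5)
  m <- tune_model(x, y, "enet", alpha_grid = c(0.2, 0.8), seed = 2)
  expect_true(m$alpha %in% c(0.2, 0.8))
  expect_gt(m$cv_r2, 0.5)
})

test_that("PCA-component models fit their rotation without leakage", {
  set.seed(31)
  n <- 90
  latent <- rnorm(n)
  x <- vapply(1:6, function(j) latent + rnorm(n, 0, 0.3), numeric(n))
  colnames(x) <- paste0("f", 1:6)
  y <- 2 * latent + rnorm(n, 0, 0.3)
  m <- tune_model(x, y, "ridge", pca = TRUE, n_components = 1:3, seed = 3)
  expect_true(m$n_components %in% 1:3)
  expect_gt(m$cv_r2, 0.8)
  v <- validate_model(m, x, y)
  expect_gt(v$r2, 0.8)
})

test_that("the winner is chosen by CV R-squared with the documented ties", {
  mk <- function(family, cv_r2, nz) {
    structure(list(family = family, cv_r2 = cv_r2, n_nonzero = nz,
                   pca = FALSE), class = "sway_model")
  }
  expect_equal(select_winner(list(mk("ridge", 0.5, 5),
                                  mk("lasso", 0.7, 3)))$family, "lasso")
  # exact tie: sparser model wins
  expect_equal(select_winner(list(mk("ridge", 0.5, 5),
                                  mk("lasso", 0.5, 3)))$family, "lasso")
  # exact tie and equal sparsity: fixed family order, ridge first
  expect_equal(select_winner(list(mk("lasso", 0.5, 5),
                                  mk("ridge", 0.5, 5)))$family, "ridge")
  w <- select_winner(list(mk("ridge", -0.2, 5)))
  expect_true(w$weak)
})

test_that("validation is leak-free: shuffling outcomes never refits", {
  set.seed(41)
  x <- matrix(rnorm(100 * 5), 100, 5)
  y <- drop(x %*% c(1, -1, 0, 0, 0)) + rnorm(100, 0, 0.3)
  tr <- 1:80
  m1 <- tune_model(x[tr, ], y[tr], "ridge", seed = 5)
  v1 <- validate_model(m1, x[-tr, ], y[-tr])
  m2 <- tune_model(x[tr, ], y[tr], "ridge", seed = 5)
  v2 <- validate_model(m2, x[-tr, ], sample(y[-tr]))
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$a0, m2$a0)
  expect_false(isTRUE(all.equal(v1$r2, v2$r2)))
})

test_that("degenerate validation predictions are flagged, not fatal", {
  set.seed(51)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- rnorm(60)
  m <- tune_model(x[1:40, ], y[1:40], "lasso",
                  lambda = c(1e3), seed = 1)     # heavy penalty: intercept only
  v <- validate_model(m, x[41:60, ], y[41:60])
  expect_true(is.na(v$r))
})

test_that("the best single predictor is the top-correlated univariate fit", {
  set.seed(61)
  n <- 100
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- 2 * x[, "c"] + rnorm(n, 0, 0.4)
  bs <- best_single_predictor(x, y)
  expect_equal(bs$name, "c")
  fit <- lm(y ~ x[, "c"])
  expect_equal(bs$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  v <- validate_single(bs, x, y)
  expect_gt(v$r2, 0.9)
  expect_lte(abs(v$ccc), abs(v$r) + 1e-12)
})

test_that("model_report returns consistent winner and single metrics", {
  sim <- simulate_biomarker_cohort(150, n_sway = 8, n_drift = 5,
                                   load_drift = 0.8, seed = 9)
  x <- cbind(sim$x_sway, sim$x_drift)
  tr <- 1:120
  rep <- model_report(x[tr, ], sim$y[tr], x[-tr, ], sim$y[-tr],
                      families = c("ridge", "lasso"), seed = 2)
  expect_s3_class(rep$winner, "sway_model")
  expect_lte(abs(rep$validation$ccc), abs(rep$validation$r) + 1e-12)
  expect_lte(abs(rep$single_validation$ccc),
             abs(rep$single_validation$r) + 1e-12)
  expect_gt(rep$validation$r2, 0.5)
})

test_that("median imputation reuses training medians downstream", {
  x <- matrix(c(1, 2, NA, 4, 10, NA, 30, 40), 4, 2)
  imp <- impute_median(x)
  expect_equal(imp$x[3, 1], 2)
  new <- impute_median(matrix(c(NA, NA), 1, 2), medians = imp$medians)
  expect_equal(as.vector(new$x), imp$medians, ignore_attr = TRUE)
})
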