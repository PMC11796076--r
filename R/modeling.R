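#' Split a cohort into training and validation subjects
#'
#' Subject-level 80/20 split, assigned before any analysis touches the
#' outcomes; deterministic under `seed`.  All trials of a subject share its
#' split label.
#'
#' @param cohort cohort tibble with unique `subject_id`.
#' @param train_fraction fraction of subjects assigned to training.
#' @param seed integer seed.
#' @return the cohort with a `split` column (`"train"` / `"validation"`).
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (anyDuplicated(cohort$subject_id)) stop("subject_id must be unique")
  n <- nrow(cohort)
  n_train <- round(n * train_fraction)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  cohort$split <- "validation"
  cohort$split[idx] <- "train"
  cohort
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two series, penalizing both scale and location shifts:
#' `2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments.  Satisfies `|CCC| <= |r|`.
#'
#' @param x,y numeric vectors of equal length.
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(NA_real_)
  2 * cxy / denom
}

r2_score <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

#' Median imputation of a feature matrix
#'
#' Column medians are computed on the training matrix and reused for any
#' later matrix (no validation leakage).
#'
#' @param x numeric matrix.
#' @param medians optional previously computed medians.
#' @return list with `x` (imputed) and `medians`.
#' @export
impute_median <- function(x, medians = NULL) {
  x <- as.matrix(x)
  if (is.null(medians)) {
    medians <- apply(x, 2, median, na.rm = TRUE)
    medians[is.na(medians)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- medians[j]
  }
  list(x = x, medians = medians)
}

scale_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

scale_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$scale, "/")
}

#' Default penalty-strength grid
#' @return 13 logarithmically spaced penalties from 1e3 down to 1e-3.
#' @export
default_lambda_grid <- function() 10^seq(3, -3, length.out = 13)

# glmnet needs >= 2 columns; pad single-component designs with a zero column.
pad2 <- function(z) {
  if (ncol(z) >= 2) return(z)
  cbind(z, `.pad` = 0)
}

fit_penalized <- function(x, y, alpha, lambda) {
  glmnet::glmnet(pad2(x), y, alpha = alpha, lambda = sort(lambda,
                 decreasing = TRUE), standardize = FALSE, family = "gaussian")
}

predict_penalized <- function(fit, x, lambda) {
  as.vector(glmnet::predict.glmnet(fit, newx = pad2(x), s = lambda))
}

coef_penalized <- function(fit, lambda, p) {
  cf <- as.vector(glmnet::coef.glmnet(fit, s = lambda))
  list(a0 = cf[1], beta = cf[2:(p + 1)])
}

#' Tune a regularized linear model by cross-validation
#'
#' Grid-searches the penalty strength (and elastic-net mixing weight, and
#' for PCA variants the component count) by k-fold cross-validation on the
#' training data, scoring each grid point by the mean held-out-fold
#' R-squared, then refits the best configuration on the full training set.
#' Features are z-scored with fold-training (and finally full-training)
#' means and standard deviations; PCA rotations are likewise fitted on the
#' training folds only, so no held-out information leaks into tuning.
#'
#' @param x numeric feature matrix (training subjects x biomarkers), with
#'   column names; missing cells are median-imputed from the training data.
#' @param y numeric outcome, no missing values.
#' @param family `"ridge"` (mixing 0), `"lasso"` (mixing 1) or `"enet"`
#'   (mixing searched over `alpha_grid`).
#' @param pca if `TRUE`, the model is fitted on leading principal
#'   components of the standardized features, with the component count
#'   searched over `n_components`.
#' @param lambda penalty-strength grid.
#' @param alpha_grid elastic-net mixing grid.
#' @param n_components component-count grid for PCA variants (default
#'   `1:min(10, ncol(x))`).
#' @param n_folds number of cross-validation folds.
#' @param one_se apply the one-standard-error rule: among configurations
#'   whose mean CV R-squared is within one standard error of the best, take
#'   the most regularized (largest penalty, then fewest components).  This
#'   is the conventional guard against overselection along a penalty path;
#'   set `FALSE` to take the raw CV maximum.
#' @param seed integer seed for the fold assignment.
#' @return object of class `sway_model`: winning hyperparameters, mean CV
#'   R-squared (`cv_r2`), the full CV table, and the refitted coefficients
#'   expressed on the standardized original features.
#' @export
tune_model <- function(x, y, family = c("ridge", "lasso", "enet"),
                       pca = FALSE, lambda = default_lambda_grid(),
                       alpha_grid = seq(0.1, 0.9, by = 0.1),
                       n_components = NULL, n_folds = 5, one_se = TRUE,
                       seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%02d", seq_len(ncol(x)))
  stopifnot(length(y) == nrow(x), !anyNA(y))
  if (ncol(x) < 2) stop("tune_model: need at least 2 features")
  imp <- impute_median(x)
  x <- imp$x
  n <- nrow(x)
  if (n < n_folds) stop("tune_model: fewer training subjects than folds")
  lambda <- sort(lambda, decreasing = TRUE)
  alphas <- switch(family, ridge = 0, lasso = 1, enet = alpha_grid)
  comps <- if (!pca) NA_integer_ else {
    n_components %||% seq_len(min(10, ncol(x)))
  }
  folds <- withr::with_seed(seed,
                            sample(rep(seq_len(n_folds), length.out = n)))

  cv <- list()
  for (a in alphas) {
    # accumulate per-fold R^2 for each (m, lambda) cell
    acc <- array(NA_real_, dim = c(length(comps), length(lambda), n_folds))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      sc <- scale_fit(x[tr, , drop = FALSE])
      xs_tr <- scale_apply(x[tr, , drop = FALSE], sc)
      xs_va <- scale_apply(x[!tr, , drop = FALSE], sc)
      y_tr <- y[tr]; y_va <- y[!tr]
      ss_tot <- sum((y_va - mean(y_va))^2)
      if (ss_tot == 0) next
      if (!pca) {
        fit <- fit_penalized(xs_tr, y_tr, a, lambda)
        pred <- glmnet::predict.glmnet(fit, newx = pad2(xs_va), s = lambda)
        acc[1, , f] <- 1 - colSums((pred - y_va)^2) / ss_tot
      } else {
        pr <- stats::prcomp(xs_tr, center = FALSE, scale. = FALSE)
        for (mi in seq_along(comps)) {
          m <- min(comps[mi], ncol(pr$rotation))
          z_tr <- xs_tr %*% pr$rotation[, seq_len(m), drop = FALSE]
          z_va <- xs_va %*% pr$rotation[, seq_len(m), drop = FALSE]
          fit <- fit_penalized(z_tr, y_tr, a, lambda)
          pred <- glmnet::predict.glmnet(fit, newx = pad2(z_va), s = lambda)
          acc[mi, , f] <- 1 - colSums((pred - y_va)^2) / ss_tot
        }
      }
    }
    mean_r2 <- apply(acc, c(1, 2), mean, na.rm = TRUE)
    se_r2 <- apply(acc, c(1, 2), function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(0)
      sd(v) / sqrt(length(v))
    })
    for (mi in seq_along(comps)) {
      cv[[length(cv) + 1]] <- tibble::tibble(
        alpha = a, n_components = comps[mi], lambda = lambda,
        cv_r2 = mean_r2[mi, ], cv_se = se_r2[mi, ])
    }
  }
  cv_table <- dplyr::bind_rows(cv)
  top <- which.max(cv_table$cv_r2)
  if (one_se) {
    thr <- cv_table$cv_r2[top] - cv_table$cv_se[top]
    ok <- which(cv_table$cv_r2 >= thr)
    # most regularized admissible configuration: largest penalty, then
    # fewest components, then CV score as the final arbiter
    ok <- ok[order(-cv_table$lambda[ok], cv_table$n_components[ok],
                   -cv_table$cv_r2[ok])]
    best <- cv_table[ok[1], ]
  } else {
    best <- cv_table[top, ]
  }

  # refit the winning configuration on the full training set
  sc <- scale_fit(x)
  xs <- scale_apply(x, sc)
  if (!pca) {
    fit <- fit_penalized(xs, y, best$alpha, lambda)
    cf <- coef_penalized(fit, best$lambda, ncol(xs))
    beta <- stats::setNames(cf$beta, colnames(x))
    rotation <- NULL
  } else {
    pr <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    m <- min(best$n_components, ncol(pr$rotation))
    rotation <- pr$rotation[, seq_len(m), drop = FALSE]
    z <- xs %*% rotation
    fit <- fit_penalized(z, y, best$alpha, lambda)
    cf <- coef_penalized(fit, best$lambda, ncol(z))
    beta <- stats::setNames(as.vector(rotation %*% cf$beta), colnames(x))
  }
  structure(list(
    family = family, pca = pca, alpha = best$alpha,
    lambda = best$lambda, n_components = best$n_components,
    cv_r2 = best$cv_r2, cv_table = cv_table,
    center = sc$center, scale = sc$scale, medians = imp$medians,
    a0 = cf$a0, beta = beta,
    n_nonzero = sum(abs(cf$beta) > 1e-12),
    n_folds = n_folds, seed = seed
  ), class = "sway_model")
}

#' Predict from a tuned model
#' @param object a `sway_model`.
#' @param newx feature matrix with the training columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.sway_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (!is.null(colnames(newx))) {
    newx <- newx[, names(object$beta), drop = FALSE]
  } else if (ncol(newx) != length(object$beta)) {
    stop("predict.sway_model: unnamed matrix with wrong number of columns")
  }
  newx <- impute_median(newx, medians = object$medians)$x
  xs <- scale_apply(newx, list(center = object$center,
                               scale = object$scale))
  as.vector(object$a0 + xs %*% object$beta)
}

#' @export
print.sway_model <- function(x, ...) {
  cat("<sway_model> ", x$family, if (x$pca) " (PCA)" else "",
      ": lambda = ", signif(x$lambda, 3),
      if (x$family == "enet") paste0(", mixing = ", x$alpha) else "",
      if (x$pca) paste0(", components = ", x$n_components) else "",
      ", CV R^2 = ", round(x$cv_r2, 3),
      ", nonzero = ", x$n_nonzero, "\n", sep = "")
  invisible(x)
}

#' Select the winning model family by cross-validated R-squared
#'
#' Ties (within 1e-12) are broken by fewer nonzero coefficients, then by
#' the fixed family order ridge, elastic net, lasso.  A winner whose CV
#' R-squared is non-positive is flagged `weak`.
#'
#' @param models list of tuned `sway_model`s.
#' @return the winning model, with a logical `weak` element added.
#' @export
select_winner <- function(models) {
  if (length(models) == 0) stop("select_winner: no models")
  r2 <- vapply(models, function(m) m$cv_r2, numeric(1))
  cand <- which(r2 > max(r2) - 1e-12)
  if (length(cand) > 1) {
    nz <- vapply(models[cand], function(m) m$n_nonzero, numeric(1))
    cand <- cand[nz == min(nz)]
    if (length(cand) > 1) {
      rank <- match(vapply(models[cand], function(m) m$family, character(1)),
                    c("ridge", "enet", "lasso"))
      cand <- cand[which.min(rank)]
    }
  }
  winner <- models[[cand[1]]]
  winner$weak <- winner$cv_r2 <= 0
  winner
}

validation_metrics <- function(obs, pred) {
  r <- if (sd(pred) == 0 || sd(obs) == 0) NA_real_ else
    stats::cor(obs, pred)
  tibble::tibble(r = r, r2 = r2_score(obs, pred), ccc = ccc(obs, pred),
                 n = length(obs))
}

#' Validate a model on the held-out split
#'
#' Computes Pearson r, R-squared (`1 - SS_res / SS_tot`) and Lin's CCC
#' between predictions and observations.  Lin's inequality
#' `|CCC| <= |r|` is asserted on every report.
#'
#' @param model a `sway_model`.
#' @param x_val,y_val validation features and outcome.
#' @return one-row tibble `r, r2, ccc, n`.
#' @export
validate_model <- function(model, x_val, y_val) {
  ok <- !is.na(y_val)
  pred <- predict(model, x_val[ok, , drop = FALSE])
  out <- validation_metrics(y_val[ok], pred)
  if (!is.na(out$r) && !is.na(out$ccc) && out$ccc > abs(out$r) + 1e-8) {
    warning("CCC exceeded |r|; metrics inconsistent")
  }
  out
}

#' Best single predictor: univariate reference model
#'
#' The feature with the highest absolute training-set Pearson correlation
#' to the outcome, fitted by univariate ordinary least squares on the
#' training split.
#'
#' @param x_train,y_train training features and outcome.
#' @return list with `name`, `intercept`, `slope`, `r_train`.
#' @export
best_single_predictor <- function(x_train, y_train) {
  x_train <- as.matrix(x_train)
  cors <- suppressWarnings(
    stats::cor(x_train, y_train, use = "pairwise.complete.obs"))
  cors[is.na(cors)] <- 0
  j <- which.max(abs(cors))
  xj <- x_train[, j]
  fit <- lm(y_train ~ xj)
  list(name = colnames(x_train)[j],
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_train = cors[j])
}

#' Validate the best single predictor on the held-out split
#' @param single a [best_single_predictor()] object.
#' @param x_val,y_val validation features and outcome.
#' @return one-row tibble `r, r2, ccc, n`.
#' @export
validate_single <- function(single, x_val, y_val) {
  xv <- as.matrix(x_val)[, single$name]
  ok <- !is.na(y_val) & !is.na(xv)
  pred <- single$intercept + single$slope * xv[ok]
  validation_metrics(y_val[ok], pred)
}

#' Tune all requested families, pick a winner and validate it
#'
#' Runs [tune_model()] for each family (optionally also the PCA variants),
#' selects the winner by CV R-squared, refits/validates on the held-out
#' split, and compares against the best single predictor.
#'
#' @param x_train,y_train training features/outcome.
#' @param x_val,y_val validation features/outcome.
#' @param families model families to tune.
#' @param use_pca also tune PCA-component variants of each family.
#' @param lambda,alpha_grid,n_folds,seed passed to [tune_model()].
#' @return list of class `model_report`: `winner` (`sway_model`),
#'   `validation` metrics, `single` (best single predictor) and
#'   `single_validation`.
#' @export
model_report <- function(x_train, y_train, x_val, y_val,
                         families = c("ridge", "lasso", "enet"),
                         use_pca = FALSE, lambda = default_lambda_grid(),
                         alpha_grid = seq(0.1, 0.9, by = 0.1),
                         n_folds = 5, seed = 1L) {
  ok <- !is.na(y_train)
  x_train <- as.matrix(x_train)[ok, , drop = FALSE]
  y_train <- y_train[ok]
  models <- list()
  for (fam in families) {
    models[[length(models) + 1]] <-
      tune_model(x_train, y_train, fam, pca = FALSE, lambda = lambda,
                 alpha_grid = alpha_grid, n_folds = n_folds, seed = seed)
    if (use_pca) {
      models[[length(models) + 1]] <-
        tune_model(x_train, y_train, fam, pca = TRUE, lambda = lambda,
                   alpha_grid = alpha_grid, n_folds = n_folds, seed = seed)
    }
  }
  winner <- select_winner(models)
  single <- best_single_predictor(x_train, y_train)
  structure(list(
    winner = winner,
    validation = validate_model(winner, x_val, y_val),
    single = single,
    single_validation = validate_single(single, x_val, y_val),
    cv_r2 = vapply(models, function(m) m$cv_r2, numeric(1))
  ), class = "model_report")
}
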