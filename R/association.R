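#' Subject-level biomarker scores
#'
#' Collapses a (subject, trial) panel to one row per subject by averaging
#' each biomarker over the subject's non-missing (and, if flags are given,
#' non-outlier) trials.
#'
#' @param panel wide biomarker panel.
#' @param flags optional [flag_outliers()] tibble; flagged cells are
#'   excluded from the mean.
#' @return tibble with `subject_id` and one mean column per biomarker.
#' @export
subject_scores <- function(panel, flags = NULL) {
  if (!is.null(flags)) panel <- mask_outliers(panel, flags)
  dplyr::summarise(
    dplyr::group_by(panel, .data$subject_id),
    dplyr::across(dplyr::all_of(panel_biomarkers(panel)),
                  ~ ifelse(all(is.na(.x)), NA_real_, mean(.x, na.rm = TRUE))),
    .groups = "drop")
}

encode_binary <- function(x) {
  if (is.numeric(x)) return(x)
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) > 2) stop("cannot encode non-binary variable numerically")
  as.numeric(match(x, lev) - 1)
}

#' Pearson correlations of biomarkers with outcomes, with BH adjustment
#'
#' For every biomarker x target (x stratum) cell with at least `min_n`
#' complete pairs, computes the Pearson correlation and its two-sided
#' p-value, then Benjamini-Hochberg-adjusts the p-values within the whole
#' report (one family per call, mirroring one figure's adjustment).  Binary
#' character targets (e.g. sex) are encoded 0/1, giving the point-biserial
#' correlation.  Constant biomarkers or outcomes yield a missing cell.
#'
#' @param scores subject-level biomarker tibble from [subject_scores()].
#' @param cohort cohort table with `subject_id` and the target columns
#'   (plus `diagnosis` when `strata` are used).
#' @param biomarkers biomarker column names to correlate.
#' @param targets outcome/demographic column names.
#' @param strata optional diagnosis groups to stratify by; groups with
#'   fewer than `min_stratum_n` subjects are dropped.
#' @param min_n minimum complete pairs per cell.
#' @param min_stratum_n minimum subjects for a stratum to be analysed.
#' @param alpha FDR level recorded in the report.
#' @return tibble: `stratum, biomarker, target, r, p_value, q_value, n`.
#' @export
correlate_biomarkers <- function(scores, cohort, biomarkers, targets,
                                 strata = NULL, min_n = 3,
                                 min_stratum_n = 10, alpha = 0.05) {
  df <- dplyr::inner_join(scores, cohort, by = "subject_id")
  strata_sets <- if (is.null(strata)) {
    list(all = rep(TRUE, nrow(df)))
  } else {
    counts <- table(df$diagnosis)
    use <- intersect(strata, names(counts)[counts >= min_stratum_n])
    stats::setNames(lapply(use, function(g) df$diagnosis == g), use)
  }
  rows <- list()
  for (s in names(strata_sets)) {
    sub <- df[strata_sets[[s]], ]
    for (tg in targets) {
      y_all <- encode_binary(sub[[tg]])
      for (b in biomarkers) {
        x <- sub[[b]]
        ok <- !is.na(x) & !is.na(y_all)
        n <- sum(ok)
        if (n < min_n || sd(x[ok]) == 0 || sd(y_all[ok]) == 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            stratum = s, biomarker = b, target = tg, r = NA_real_,
            p_value = NA_real_, n = n)
          next
        }
        ct <- stats::cor.test(x[ok], y_all[ok], method = "pearson")
        rows[[length(rows) + 1]] <- tibble::tibble(
          stratum = s, biomarker = b, target = tg,
          r = unname(ct$estimate), p_value = ct$p.value, n = n)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "alpha") <- alpha
  out
}

#' Fit the healthy-reference age regression and 95% prediction band
#'
#' Ordinary least squares of a biomarker on age in the reference (healthy
#' volunteer) group, with the textbook prediction interval for a new
#' observation at age `x`:
#' `fit(x) +/- t(1 - (1-level)/2, n-2) * s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)`.
#'
#' @param scores subject-level biomarker tibble.
#' @param cohort cohort table with `subject_id`, `age`, `diagnosis`.
#' @param biomarker biomarker column name.
#' @param reference_group diagnosis label of the reference cohort.
#' @param level prediction-interval level.
#' @param min_n minimum reference subjects.
#' @return object of class `age_band`: intercept, slope, residual sd,
#'   `n`, `age_mean`, `sxx`, reference age range, `level`, `biomarker`.
#' @export
fit_age_band <- function(scores, cohort, biomarker, reference_group = "HV",
                         level = 0.95, min_n = 5) {
  df <- dplyr::inner_join(scores[, c("subject_id", biomarker)],
                          cohort[, c("subject_id", "age", "diagnosis")],
                          by = "subject_id")
  ref <- df[df$diagnosis == reference_group &
              !is.na(df[[biomarker]]) & !is.na(df$age), ]
  n <- nrow(ref)
  if (n < min_n) {
    stop("fit_age_band: fewer than ", min_n, " usable ", reference_group,
         " subjects")
  }
  if (sd(ref$age) == 0) stop("fit_age_band: degenerate age variance")
  y <- ref[[biomarker]]
  fit <- lm(y ~ age, data = ref)
  res <- stats::residuals(fit)
  s <- sqrt(sum(res^2) / (n - 2))
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    sigma = s, n = n, age_mean = mean(ref$age),
    sxx = sum((ref$age - mean(ref$age))^2),
    age_range = range(ref$age), level = level,
    biomarker = biomarker, reference_group = reference_group
  ), class = "age_band")
}

#' Evaluate an age prediction band
#'
#' @param band an [fit_age_band()] object.
#' @param age ages at which to evaluate.
#' @return tibble `age, fit, lower, upper`.
#' @export
predict_band <- function(band, age) {
  fit <- band$intercept + band$slope * age
  tq <- stats::qt(1 - (1 - band$level) / 2, band$n - 2)
  half <- tq * band$sigma *
    sqrt(1 + 1 / band$n + (age - band$age_mean)^2 / band$sxx)
  tibble::tibble(age = age, fit = fit, lower = fit - half,
                 upper = fit + half)
}

#' Age residuals of a biomarker relative to the reference regression
#'
#' @param band an [fit_age_band()] object.
#' @param scores subject-level biomarker tibble.
#' @param cohort cohort table with `subject_id`, `age`, `diagnosis`.
#' @return tibble `subject_id, diagnosis, age, value, residual`.
#' @export
age_residuals <- function(band, scores, cohort) {
  df <- dplyr::inner_join(scores[, c("subject_id", band$biomarker)],
                          cohort[, c("subject_id", "age", "diagnosis")],
                          by = "subject_id")
  names(df)[names(df) == band$biomarker] <- "value"
  df$residual <- df$value - (band$intercept + band$slope * df$age)
  df[!is.na(df$value) & !is.na(df$age),
     c("subject_id", "diagnosis", "age", "value", "residual")]
}

#' Call abnormal biomarker values beyond the aging band
#'
#' A subject is abnormal when the observed value exceeds the upper
#' prediction bound at the subject's age.  Because increased sway is the
#' direction of dysfunction, the call is one-sided, so the bound used is
#' the one-sided upper prediction limit at the band's level (for a 95%
#' band, `fit + t(0.95, n-2) * s * sqrt(1 + 1/n + (x - xbar)^2 / Sxx)`,
#' giving a 5% expected exceedance in the reference population).  Subjects
#' whose age lies outside the reference age range by more than
#' `extrapolation_window` years are flagged extrapolated.
#'
#' @param band an [fit_age_band()] object.
#' @param scores subject-level biomarker tibble.
#' @param cohort cohort table.
#' @param extrapolation_window years beyond the reference age range before a
#'   call is flagged extrapolated.
#' @return tibble `subject_id, diagnosis, age, value, upper, abnormal,
#'   extrapolated`.
#' @export
call_abnormal <- function(band, scores, cohort, extrapolation_window = 10) {
  df <- age_residuals(band, scores, cohort)
  fit <- band$intercept + band$slope * df$age
  tq <- stats::qt(band$level, band$n - 2)      # one-sided upper limit
  df$upper <- fit + tq * band$sigma *
    sqrt(1 + 1 / band$n + (df$age - band$age_mean)^2 / band$sxx)
  df$abnormal <- df$value > df$upper
  df$extrapolated <- df$age < band$age_range[1] - extrapolation_window |
    df$age > band$age_range[2] + extrapolation_window
  df[, c("subject_id", "diagnosis", "age", "value", "upper", "abnormal",
         "extrapolated")]
}

#' Fraction of abnormal calls per diagnosis group
#'
#' @param calls a [call_abnormal()] tibble.
#' @param groups group labels to report (default: those present); groups
#'   with no subjects get `NA`.
#' @return tibble `diagnosis, n, n_abnormal, fraction_abnormal`.
#' @export
abnormal_fractions <- function(calls, groups = NULL) {
  if (is.null(groups)) groups <- sort(unique(calls$diagnosis))
  rows <- lapply(groups, function(g) {
    sub <- calls[calls$diagnosis == g, ]
    n <- nrow(sub)
    tibble::tibble(diagnosis = g, n = n,
                   n_abnormal = if (n == 0) NA_integer_ else
                     sum(sub$abnormal),
                   fraction_abnormal = if (n == 0) NA_real_ else
                     mean(sub$abnormal))
  })
  dplyr::bind_rows(rows)
}

#' Pairwise Wilcoxon rank-sum comparisons of groups, with BH adjustment
#'
#' Tests every unordered pair of groups on a numeric value (typically the
#' age residuals of a biomarker); p-values are Benjamini-Hochberg-adjusted
#' across the pair family.  Groups with fewer than `min_n` observations are
#' skipped.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param min_n minimum group size.
#' @param alpha FDR level recorded in the report.
#' @return tibble `group1, group2, n1, n2, p_value, q_value`.
#' @export
compare_groups <- function(values, groups, min_n = 2, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  counts <- table(groups)
  use <- names(counts)[counts >= min_n]
  if (length(use) < 2) stop("compare_groups: fewer than 2 usable groups")
  pairs <- utils::combn(sort(use), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x <- values[groups == g1]; y <- values[groups == g2]
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    tibble::tibble(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "alpha") <- alpha
  out
}
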