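#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way, absolute-agreement, single-measurement ICC with trials treated
#' as raters.  From the two-way ANOVA decomposition into between-subject
#' (`MSR`), between-trial (`MSC`) and residual (`MSE`) mean squares:
#'
#' `ICC = (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))`
#'
#' The p-value tests zero reliability via `F = MSR / MSE` with
#' `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' @param ratings numeric matrix, `n` subjects x `k` trials, no missing
#'   cells (complete cases are the caller's responsibility).
#' @return list with `icc`, `p_value`, `n`, `k`; `icc` is `NA` when both
#'   the between-subject and residual variances are zero.
#' @export
icc21 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3) stop("icc21: need at least 3 subjects")
  if (k < 2) stop("icc21: need at least 2 trials")
  if (anyNA(ratings)) stop("icc21: missing cells not allowed")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(rowm, colm, `+`) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (mse == 0 && msr == 0) {
    return(list(icc = NA_real_, p_value = NA_real_, n = n, k = k))
  }
  icc <- if (denom == 0) NA_real_ else (msr - mse) / denom
  p <- if (mse == 0) 0 else
    pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, p_value = p, n = n, k = k)
}

#' Test-retest reliability screen of a biomarker panel
#'
#' Computes ICC(2,1) per biomarker over a pair of trials (by default the
#' first two in order of trial id; any pairing, e.g. first in-clinic vs
#' closest at-home, can be passed explicitly), adjusts the F-test p-values
#' by Benjamini-Hochberg, and marks biomarkers with `icc > cutoff` as
#' reliable.  Complete-case per biomarker: a subject missing either trial's
#' value (including outlier-masked cells) is dropped for that biomarker
#' only; biomarkers with fewer than `min_subjects` complete subjects are
#' reported with `NA`.
#'
#' @param panel wide biomarker panel (optionally already outlier-masked via
#'   [mask_outliers()]).
#' @param trial_pair character vector of two trial ids; default the first
#'   two present.
#' @param cutoff reliability cutoff on the ICC (default 0.5).
#' @param alpha BH false-discovery-rate level (recorded in the report).
#' @param min_subjects minimum complete subjects per biomarker.
#' @return tibble: `biomarker, icc, p_value, q_value, n_subjects, reliable`.
#' @export
screen_reliability <- function(panel, trial_pair = NULL, cutoff = 0.5,
                               alpha = 0.05, min_subjects = 3) {
  trials <- sort(unique(panel$trial_id))
  if (is.null(trial_pair)) {
    if (length(trials) < 2) stop("screen_reliability: need at least 2 trials")
    trial_pair <- trials[1:2]
  }
  stopifnot(length(trial_pair) == 2)
  biomarkers <- panel_biomarkers(panel)
  t1 <- panel[panel$trial_id == trial_pair[1], ]
  t2 <- panel[panel$trial_id == trial_pair[2], ]
  common <- intersect(t1$subject_id, t2$subject_id)
  t1 <- t1[match(common, t1$subject_id), ]
  t2 <- t2[match(common, t2$subject_id), ]

  skipped <- character(0)
  res <- lapply(biomarkers, function(b) {
    m <- cbind(t1[[b]], t2[[b]])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < min_subjects) {
      skipped <<- c(skipped, b)
      return(tibble::tibble(biomarker = b, icc = NA_real_,
                            p_value = NA_real_, n_subjects = nrow(m)))
    }
    r <- icc21(m)
    tibble::tibble(biomarker = b, icc = r$icc, p_value = r$p_value,
                   n_subjects = r$n)
  })
  out <- dplyr::bind_rows(res)
  if (length(skipped) > 0) {
    warning("biomarkers with fewer than ", min_subjects,
            " complete subjects: ", paste(skipped, collapse = ", "))
  }
  if (all(is.na(out$icc))) {
    stop("screen_reliability: no biomarker with sufficient subjects")
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$reliable <- !is.na(out$icc) & out$icc > cutoff
  attr(out, "cutoff") <- cutoff
  attr(out, "alpha") <- alpha
  attr(out, "trial_pair") <- trial_pair
  out
}

#' Names of the biomarkers passing the reliability screen
#' @param report a [screen_reliability()] report.
#' @return character vector of reliable biomarker names.
#' @export
reliable_biomarkers <- function(report) {
  report$biomarker[report$reliable]
}
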