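#' Pipeline configuration
#'
#' Collects every analysis parameter of the simulate - extract - screen -
#' correlate - model pipeline.  All parameters are echoed into the output
#' manifest so each run is self-describing.
#'
#' @param out_dir output directory (created if absent).
#' @param n_subjects,n_trials cohort size when simulating.
#' @param seed global seed; every stage derives its own substream.
#' @param band spectral band `c(b1, b2)`, Hz.
#' @param target_duration trim target, seconds.
#' @param icc_cutoff reliability cutoff on the ICC.
#' @param fence_multiplier IQR fence multiplier for outlier flagging.
#' @param alpha BH false-discovery-rate level.
#' @param train_fraction training split fraction.
#' @param outcomes global/clinical outcomes to model from sway (and, for
#'   the global scales, combined) biomarkers.
#' @param drift_outcome outcome modeled from drift biomarkers (the
#'   cerebellar subpanel of the dominant hand by default, which is what
#'   drift biomarkers track).
#' @param band_biomarker biomarker for the age prediction band (used if
#'   reliable; otherwise the highest-ICC reliable biomarker is taken).
#' @param families model families to tune.
#' @param use_pca also tune PCA-component model variants.
#' @param lambda,alpha_grid,n_folds model tuning grids.
#' @param sway_params,cohort_params optional simulation parameter objects
#'   (defaults are constructed from `n_subjects`/`n_trials`/`seed`).
#' @param traces_path,cohort_path optional existing input CSVs; when
#'   `traces_path` is given, nothing is simulated and `cohort_path` must
#'   also be given if any modeling/association outcome is requested.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            n_subjects = 20, n_trials = 2, seed = 1L,
                            band = c(0.15, 10), target_duration = 9,
                            icc_cutoff = 0.5, fence_multiplier = 1.5,
                            alpha = 0.05, train_fraction = 0.8,
                            outcomes = c("edss", "combiwise", "neurex",
                                         "neurex_sway"),
                            drift_outcome = "neurex_cerebellar_dom",
                            band_biomarker = "RMS_Net_ECFT",
                            families = c("ridge", "lasso", "enet"),
                            use_pca = FALSE,
                            lambda = default_lambda_grid(),
                            alpha_grid = seq(0.1, 0.9, by = 0.1),
                            n_folds = 5,
                            sway_params = NULL, cohort_params = NULL,
                            traces_path = NULL, cohort_path = NULL) {
  if (missing(out_dir) || is.null(out_dir)) {
    stop("pipeline_config: 'out_dir' is required")
  }
  if (!is.null(traces_path) && is.null(cohort_path) &&
      (length(outcomes) > 0 || length(drift_outcome) > 0)) {
    stop("pipeline_config: 'cohort_path' is required when modeling ",
         "outcomes are requested with external traces")
  }
  stopifnot(band[1] < band[2], icc_cutoff >= -1, icc_cutoff <= 1,
            fence_multiplier > 0, alpha > 0, alpha < 1,
            train_fraction > 0, train_fraction < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_log <- function(lines, path) {
  for (l in lines) message(l)
  cat(lines, file = path, sep = "\n", append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) raw traces and a cohort table; split subjects
#' 80/20 before any analysis touches the outcomes; extract features and
#' assemble the 60 + 16 biomarker panel; flag outliers against training
#' fences; screen test-retest reliability on training subjects; correlate
#' reliable biomarkers with demographics and clinical/imaging outcomes;
#' fit the healthy-reference age band, call abnormal subjects and compare
#' groups; tune, select and validate predictive models; and write every
#' artifact with a content-hash manifest.
#'
#' @param config a [pipeline_config()] object.
#' @return invisibly, a list with the main results and the artifact
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  if (file.exists(log_path)) file.remove(log_path)
  out <- function(name) file.path(config$out_dir, name)
  written <- character(0)
  results <- list()

  # -- stage: simulate or load ------------------------------------------
  if (is.null(config$traces_path)) {
    sway <- config$sway_params %||%
      sway_sim_params(config$n_subjects, config$n_trials,
                      seed = derive_seed(config$seed, 101L))
    cp <- config$cohort_params %||%
      cohort_sim_params(seed = derive_seed(config$seed, 102L))
    sim <- simulate_cohort(sway, cp)
    traces <- sim$traces
    cohort <- sim$cohort
    write_traces(traces, out("traces.csv"))
    write_cohort(cohort, out("cohort.csv"))
    jsonlite::write_json(sim$truth, out("ground_truth.json"),
                         auto_unbox = TRUE, digits = 10)
    written <- c(written, "traces.csv", "cohort.csv", "ground_truth.json")
    pipeline_log(sprintf("simulate: %d subjects x %d trials",
                         sway$n_subjects, sway$n_trials), log_path)
  } else {
    traces <- read_traces(config$traces_path)
    cohort <- readr::read_csv(config$cohort_path, show_col_types = FALSE)
    pipeline_log(sprintf("load: %s", config$traces_path), log_path)
  }

  # -- stage: split (before all analyses) -------------------------------
  cohort <- split_cohort(cohort, config$train_fraction,
                         seed = derive_seed(config$seed, 103L))
  train_ids <- cohort$subject_id[cohort$split == "train"]

  # -- stage: extract ----------------------------------------------------
  features <- extract_features(traces, band = config$band,
                               target_duration = config$target_duration)
  panel <- build_panel(features,
                       cohort[, c("subject_id", "dominant_hand")])
  readr::write_csv(panel, out("panel.csv"))
  written <- c(written, "panel.csv")
  n_sway <- sum(sway_biomarker_names() %in% names(panel))
  n_drift <- sum(drift_biomarker_names() %in% names(panel))
  pipeline_log(sprintf("extract: %d sway / %d drift biomarkers",
                       n_sway, n_drift), log_path)

  # -- stage: outliers and reliability ----------------------------------
  flags <- flag_outliers(panel, reference_ids = train_ids,
                         fence_multiplier = config$fence_multiplier)
  readr::write_csv(flags, out("flags.csv"))
  masked <- mask_outliers(panel, flags)
  rel <- screen_reliability(masked[masked$subject_id %in% train_ids, ],
                            cutoff = config$icc_cutoff,
                            alpha = config$alpha)
  readr::write_csv(rel, out("reliability.csv"))
  written <- c(written, "flags.csv", "reliability.csv")
  reliable <- reliable_biomarkers(rel)
  pipeline_log(sprintf("reliability: %d of %d biomarkers with ICC > %.2f",
                       length(reliable), nrow(rel), config$icc_cutoff),
               log_path)
  results$reliability <- rel

  # -- stage: correlations ----------------------------------------------
  scores <- subject_scores(panel, flags)
  train_scores <- scores[scores$subject_id %in% train_ids, ]
  clinical_targets <- intersect(
    unique(c(config$outcomes, config$drift_outcome,
             grep("^mri_", names(cohort), value = TRUE))),
    names(cohort))
  if (length(reliable) > 0 && length(clinical_targets) > 0) {
    clin_cor <- correlate_biomarkers(train_scores, cohort, reliable,
                                     clinical_targets,
                                     alpha = config$alpha)
    demo_targets <- intersect(c("age", "sex", "height", "weight"),
                              names(cohort))
    demo_cor <- correlate_biomarkers(train_scores, cohort, reliable,
                                     demo_targets,
                                     strata = unique(cohort$diagnosis),
                                     alpha = config$alpha)
    readr::write_csv(clin_cor, out("correlations_clinical.csv"))
    readr::write_csv(demo_cor, out("correlations_demographics.csv"))
    written <- c(written, "correlations_clinical.csv",
                 "correlations_demographics.csv")
    results$clinical_correlations <- clin_cor
    results$demographic_correlations <- demo_cor
  } else {
    clin_cor <- NULL
    pipeline_log("correlate: skipped (no reliable biomarkers)", log_path)
  }

  # -- stage: age band and group comparisons ----------------------------
  band_bm <- if (config$band_biomarker %in% reliable) {
    config$band_biomarker
  } else if (length(reliable) > 0) {
    rel$biomarker[which.max(rel$icc)]
  } else {
    config$band_biomarker
  }
  band_res <- tryCatch({
    band <- fit_age_band(train_scores, cohort, band_bm)
    calls <- call_abnormal(band, scores, cohort)
    calls <- dplyr::left_join(calls,
                              cohort[, c("subject_id", "split")],
                              by = "subject_id")
    fractions <- abnormal_fractions(calls)
    resid <- age_residuals(band, scores, cohort)
    comparisons <- tryCatch(
      compare_groups(resid$residual, resid$diagnosis,
                     alpha = config$alpha),
      error = function(e) NULL)
    jsonlite::write_json(unclass(band), out("age_band.json"),
                         auto_unbox = TRUE, digits = 10)
    readr::write_csv(calls, out("abnormal_calls.csv"))
    readr::write_csv(fractions, out("abnormal_fractions.csv"))
    if (!is.null(comparisons)) {
      readr::write_csv(comparisons, out("group_comparisons.csv"))
    }
    list(band = band, calls = calls, fractions = fractions,
         comparisons = comparisons)
  }, error = function(e) {
    pipeline_log(paste("age band: skipped -", conditionMessage(e)),
                 log_path)
    NULL
  })
  if (!is.null(band_res)) {
    written <- c(written, "age_band.json", "abnormal_calls.csv",
                 "abnormal_fractions.csv",
                 if (!is.null(band_res$comparisons)) "group_comparisons.csv")
    pipeline_log(sprintf("age band: %s on %d reference subjects",
                         band_bm, band_res$band$n), log_path)
    results$age_band <- band_res
  }

  # -- stage: modeling ---------------------------------------------------
  gate <- function(candidates) {
    if (is.null(clin_cor)) return(character(0))
    correlated <- unique(clin_cor$biomarker[!is.na(clin_cor$q_value) &
                                              clin_cor$q_value <= config$alpha])
    intersect(candidates, intersect(reliable, correlated))
  }
  sway_feats <- gate(sway_biomarker_names())
  drift_feats <- gate(drift_biomarker_names())
  model_data <- dplyr::inner_join(scores,
                                  cohort[, c("subject_id", "split",
                                             clinical_targets)],
                                  by = "subject_id")
  tr <- model_data$split == "train"
  fit_one <- function(feats, outcome, label) {
    if (length(feats) < 2) {
      pipeline_log(sprintf("model %s: skipped (%d gated features)",
                           label, length(feats)), log_path)
      return(NULL)
    }
    y_tr <- model_data[[outcome]][tr]
    if (sum(!is.na(y_tr)) < config$n_folds + 2) {
      pipeline_log(sprintf("model %s: skipped (too few outcomes)", label),
                   log_path)
      return(NULL)
    }
    x <- as.matrix(model_data[, feats])
    rep <- model_report(x[tr, , drop = FALSE], y_tr,
                        x[!tr, , drop = FALSE],
                        model_data[[outcome]][!tr],
                        families = config$families,
                        use_pca = config$use_pca,
                        lambda = config$lambda,
                        alpha_grid = config$alpha_grid,
                        n_folds = config$n_folds,
                        seed = derive_seed(config$seed, 104L))
    pipeline_log(sprintf(
      "model %s: winner %s%s (CV R^2 %.3f), validation r %.3f ccc %.3f",
      label, rep$winner$family, if (rep$winner$pca) "+PCA" else "",
      rep$winner$cv_r2, rep$validation$r, rep$validation$ccc), log_path)
    rep
  }
  reports <- list()
  for (oc in intersect(config$outcomes, names(model_data))) {
    reports[[paste0("sway_", oc)]] <- fit_one(sway_feats, oc,
                                              paste0("sway/", oc))
  }
  for (oc in intersect(config$drift_outcome, names(model_data))) {
    reports[[paste0("drift_", oc)]] <- fit_one(drift_feats, oc,
                                               paste0("drift/", oc))
  }
  for (oc in intersect(config$outcomes,
                       c("edss", "combiwise", "neurex"))) {
    reports[[paste0("combined_", oc)]] <-
      fit_one(c(sway_feats, drift_feats), oc, paste0("combined/", oc))
  }
  reports <- reports[!vapply(reports, is.null, logical(1))]
  if (length(reports) > 0) {
    serializable <- lapply(reports, function(r) {
      list(family = r$winner$family, pca = r$winner$pca,
           lambda = r$winner$lambda, alpha = r$winner$alpha,
           n_components = r$winner$n_components,
           cv_r2 = r$winner$cv_r2,
           coefficients = as.list(r$winner$beta),
           intercept = r$winner$a0,
           validation = as.list(r$validation),
           best_single = r$single$name,
           best_single_validation = as.list(r$single_validation))
    })
    jsonlite::write_json(serializable, out("models.json"),
                         auto_unbox = TRUE, digits = 10)
    written <- c(written, "models.json")
  }
  results$models <- reports

  # -- manifest ----------------------------------------------------------
  written <- unique(written)
  hashes <- tools::md5sum(file.path(config$out_dir, written))
  names(hashes) <- written
  cfg_echo <- config[c("n_subjects", "n_trials", "seed", "band",
                       "target_duration", "icc_cutoff", "fence_multiplier",
                       "alpha", "train_fraction", "outcomes",
                       "drift_outcome", "families", "use_pca", "n_folds")]
  jsonlite::write_json(list(config = cfg_echo, files = as.list(hashes)),
                       out("manifest.json"), auto_unbox = TRUE,
                       digits = 10)
  results$manifest <- hashes
  pipeline_log(sprintf("done: %d artifacts in %s", length(written),
                       config$out_dir), log_path)
  invisible(results)
}
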