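#' Simulation parameters for raw sway/drift traces
#'
#' Defines the generative model for one cohort's raw accelerometer traces.
#' Each horizontal axis is a sum of sinusoids (the `spectral_peaks`) plus
#' band-limited Gaussian noise, scaled so the designed series standard
#' deviation is `sigma_ml` / `sigma_ap` times a per-condition difficulty
#' factor and a per-subject/per-trial log-normal severity multiplier.  The
#' gravity vector is tilted by a per-subject device tilt, exercising the
#' calibration stage.
#'
#' The log10 amplitude of a trial decomposes as
#' `severity_subject + N(0, within_sd)`, with `severity_subject`
#' drawn `N(0, between_sd)` by default, so the designed test-retest ICC of a
#' log-amplitude biomarker is `between_sd^2 / (between_sd^2 + within_sd^2)`
#' (see [designed_icc()]).
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject (>= 2 for reliability analyses).
#' @param sample_rate sampling frequency, Hz.
#' @param duration recording length, seconds (trimmed to 9 s downstream).
#' @param gravity gravity magnitude, m/s^2.
#' @param tilt_deg maximum per-subject device tilt off vertical, degrees;
#'   each subject's tilt is drawn uniformly on `[0, tilt_deg]`.
#' @param sigma_ml,sigma_ap baseline (EO-FA, unit severity) standard
#'   deviation of the medio-lateral / antero-posterior acceleration, m/s^2.
#' @param condition_scale named multipliers for the stance conditions;
#'   difficulty must increase EO-FA < EO-FT < EC-FT.  Hand conditions
#'   (`left`, `right`) use a factor of 1.
#' @param spectral_peaks data frame with columns `freq` (Hz) and `power`
#'   (relative) giving the sinusoidal components; frequencies must be below
#'   the Nyquist frequency.
#' @param noise_fraction fraction of horizontal signal variance carried by
#'   band-limited Gaussian noise (0..1).
#' @param lowpass upper band edge of the noise, Hz.
#' @param between_sd,within_sd between-subject and within-subject (trial to
#'   trial) standard deviations of log10 sway amplitude.
#' @param seed integer seed; expanded into per-subject and per-trial
#'   substreams with [derive_seed()] so generation order is irrelevant.
#' @return an object of class `sway_sim_params`.
#' @export
sway_sim_params <- function(n_subjects,
                            n_trials = 2,
                            sample_rate = 50,
                            duration = 9.5,
                            gravity = 9.81,
                            tilt_deg = 8,
                            sigma_ml = 0.015,
                            sigma_ap = 0.020,
                            condition_scale = c("EO-FA" = 1, "EO-FT" = 1.6,
                                                "EC-FT" = 2.4),
                            spectral_peaks = data.frame(
                              freq = c(0.3, 0.9),
                              power = c(0.65, 0.35)),
                            noise_fraction = 0.3,
                            lowpass = 10,
                            between_sd = 0.20,
                            within_sd = 0.12,
                            seed = 1L) {
  stopifnot(n_subjects >= 1, n_trials >= 1,
            sample_rate > 0, duration > 0, gravity > 0,
            sigma_ml >= 0, sigma_ap >= 0,
            noise_fraction >= 0, noise_fraction <= 1,
            between_sd >= 0, within_sd >= 0)
  if (any(spectral_peaks$freq >= sample_rate / 2)) {
    stop("spectral component frequencies must be below the Nyquist frequency")
  }
  if (any(spectral_peaks$power < 0)) {
    stop("spectral component powers must be non-negative")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    sample_rate = sample_rate, duration = duration, gravity = gravity,
    tilt_deg = tilt_deg, sigma_ml = sigma_ml, sigma_ap = sigma_ap,
    condition_scale = condition_scale, spectral_peaks = spectral_peaks,
    noise_fraction = noise_fraction, lowpass = lowpass,
    between_sd = between_sd, within_sd = within_sd, seed = as.integer(seed)
  ), class = "sway_sim_params")
}

#' Designed intraclass correlation of a simulation
#'
#' The variance-ratio ICC implied by the amplitude variance components:
#' `between_sd^2 / (between_sd^2 + within_sd^2)`.
#'
#' @param params a [sway_sim_params()] object.
#' @return designed ICC in `[0, 1]`.
#' @export
designed_icc <- function(params) {
  b2 <- params$between_sd^2
  w2 <- params$within_sd^2
  if (b2 + w2 == 0) return(NA_real_)
  b2 / (b2 + w2)
}

sway_conditions <- c("EO-FA", "EO-FT", "EC-FT")
drift_conditions <- c("left", "right")
all_conditions <- c(sway_conditions, drift_conditions)

condition_index <- function(condition) {
  i <- match(condition, all_conditions)
  if (is.na(i)) {
    stop("unknown condition label: ", condition)
  }
  i
}

subject_id_of <- function(i) sprintf("S%03d", i)
trial_id_of <- function(j) sprintf("T%d", j)

# Per-subject latent draws (severity, tilt); same for every trial/condition.
subject_latents <- function(params, subject) {
  withr::with_seed(derive_seed(params$seed, 1L, subject), {
    list(severity = rnorm(1, 0, params$between_sd),
         tilt_angle = runif(1, 0, params$tilt_deg) * pi / 180,
         tilt_axis = runif(1, 0, 2 * pi))
  })
}

# One horizontal series with designed sd `sigma`: sinusoids with random
# phases carrying (1 - noise_fraction) of the variance, plus band-limited
# Gaussian noise carrying the rest.  Scaling is analytic (population), so the
# empirical sd converges to `sigma` as duration grows.
generate_horizontal <- function(n, sample_rate, peaks, noise_fraction,
                                lowpass, sigma) {
  if (sigma == 0) return(numeric(n))
  t <- (seq_len(n) - 1) / sample_rate
  out <- numeric(n)
  ptot <- sum(peaks$power)
  if (ptot > 0 && noise_fraction < 1) {
    for (j in seq_len(nrow(peaks))) {
      amp <- sqrt(2 * sigma^2 * (1 - noise_fraction) * peaks$power[j] / ptot)
      phi <- runif(1, 0, 2 * pi)
      out <- out + amp * sin(2 * pi * peaks$freq[j] * t + phi)
    }
  }
  if (noise_fraction > 0) {
    white <- rnorm(n)
    X <- fft(white)
    f <- sample_rate * (seq_len(n) - 1) / n
    f <- pmin(f, sample_rate - f)            # two-sided frequency axis
    keep <- f <= lowpass
    keep[1] <- FALSE                          # no DC in the noise
    frac <- sum(keep) / n
    X[!keep] <- 0
    bl <- Re(fft(X, inverse = TRUE)) / n
    out <- out + bl / sqrt(frac) * sigma * sqrt(noise_fraction)
  }
  out
}

#' Simulate one raw accelerometer trace
#'
#' Generates the tri-axial device-frame series for one subject, trial and
#' condition.  The world-frame signal is horizontal sway (M-L, A-P) on top of
#' a constant vertical gravity vector; the per-subject device tilt is applied
#' as a rotation of all samples.  The pre-rotation horizontal series are
#' attached as attributes `latent_ml` / `latent_ap` for ground-truth tests.
#'
#' @param params a [sway_sim_params()] object.
#' @param subject,trial 1-based indices within `params`.
#' @param condition one of `EO-FA`, `EO-FT`, `EC-FT` (sway) or `left`,
#'   `right` (drift).
#' @param severity optional log10 amplitude offset for the subject,
#'   overriding the default `N(0, between_sd)` subject draw (used by
#'   [simulate_cohort()] to couple traces to cohort outcomes).
#' @return a tibble with columns `subject_id`, `trial_id`, `test`,
#'   `condition`, `t_s`, `ax`, `ay`, `az`.
#' @export
simulate_trace <- function(params, subject, trial, condition,
                           severity = NULL) {
  stopifnot(inherits(params, "sway_sim_params"))
  ci <- condition_index(condition)
  if (subject < 1 || subject > params$n_subjects) stop("subject index out of bounds")
  if (trial < 1 || trial > params$n_trials) stop("trial index out of bounds")
  if (params$duration <= 0) stop("non-positive duration")

  lat <- subject_latents(params, subject)
  if (is.null(severity)) severity <- lat$severity
  cscale <- if (condition %in% names(params$condition_scale)) {
    unname(params$condition_scale[condition])
  } else 1
  n <- round(params$sample_rate * params$duration)

  series <- withr::with_seed(
    derive_seed(params$seed, 2L, subject, trial, ci), {
      w <- rnorm(1, 0, params$within_sd)
      mult <- 10^(severity + w)
      list(
        ml = generate_horizontal(n, params$sample_rate, params$spectral_peaks,
                                 params$noise_fraction, params$lowpass,
                                 params$sigma_ml * cscale * mult),
        ap = generate_horizontal(n, params$sample_rate, params$spectral_peaks,
                                 params$noise_fraction, params$lowpass,
                                 params$sigma_ap * cscale * mult))
    })

  R <- rotation_about_horizontal(lat$tilt_axis, lat$tilt_angle)
  world <- rbind(series$ml, series$ap, rep(params$gravity, n))
  dev <- R %*% world

  out <- tibble::tibble(
    subject_id = subject_id_of(subject),
    trial_id = trial_id_of(trial),
    test = if (condition %in% drift_conditions) "drift" else "sway",
    condition = condition,
    t_s = (seq_len(n) - 1) / params$sample_rate,
    ax = dev[1, ], ay = dev[2, ], az = dev[3, ])
  attr(out, "latent_ml") <- series$ml
  attr(out, "latent_ap") <- series$ap
  attr(out, "tilt_angle_deg") <- lat$tilt_angle * 180 / pi
  out
}

#' Cohort simulation parameters
#'
#' Defines how per-subject latent sway and drift severities (log10 amplitude
#' units) are generated from age, diagnosis group and biological noise, and
#' how clinical/imaging outcomes are linearly coupled to those severities.
#'
#' Severity model (per subject, per test):
#' `severity = age_slope * (age - age_ref) + group_offset + N(0, between_sd)`
#' where `between_sd` comes from the companion [sway_sim_params()].  Outcome
#' model: each outcome is `intercept + load_sway * z_sway + load_drift *
#' z_drift + N(0, noise_sd)` on its latent scale, where `z` are severities
#' rescaled by `severity_scale`, then clipped/discretized to the scale's
#' range (EDSS to 0..10 in 0.5 steps, CombiWISE to 0..100, panel scores
#' truncated at 0).
#'
#' @param group_props named proportions over diagnosis groups (must sum to 1).
#' @param age_range named list of `c(min, max)` ages per group.
#' @param age_slope,age_ref slope (log10 units per year) and reference age of
#'   the severity-age trend.
#' @param group_offsets named mean severity shift per group (log10 units).
#' @param drift_attenuation multiplier applied to slope/offsets for the drift
#'   severity (drift couples more weakly to disability).
#' @param severity_scale divisor standardizing severities before outcome
#'   loadings are applied.
#' @param loadings named list of outcome loading vectors
#'   `c(intercept, sway, drift, noise_sd)`.
#' @param seed integer seed.
#' @return an object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(
    group_props = c("HV" = 0.30, "NIND" = 0.15, "OIND" = 0.05,
                    "MS-RR" = 0.25, "MS-SP" = 0.15, "MS-PP" = 0.10),
    age_range = list("HV" = c(20, 65), "NIND" = c(25, 70),
                     "OIND" = c(25, 70), "MS-RR" = c(20, 60),
                     "MS-SP" = c(35, 70), "MS-PP" = c(35, 70)),
    age_slope = 0.006,
    age_ref = 45,
    group_offsets = c("HV" = 0, "NIND" = 0.05, "OIND" = 0.08,
                      "MS-RR" = 0.12, "MS-SP" = 0.28, "MS-PP" = 0.34),
    drift_attenuation = 0.6,
    severity_scale = 0.25,
    loadings = list(
      edss      = c(intercept = 2.5, sway = 1.8, drift = 0.9, noise_sd = 0.9),
      combiwise = c(intercept = 25,  sway = 16,  drift = 8,   noise_sd = 7),
      neurex_base = c(intercept = 60, sway = 40, drift = 20, noise_sd = 18),
      stance_gait = c(intercept = 6, sway = 5, drift = 0, noise_sd = 2),
      cerebellar_le = c(intercept = 4, sway = 3.2, drift = 0, noise_sd = 1.6),
      proprio_le = c(intercept = 3, sway = 2.4, drift = 0, noise_sd = 1.4),
      motoric_hand = c(intercept = 2.5, sway = 0, drift = 1.6, noise_sd = 1.1),
      cerebellar_hand = c(intercept = 3, sway = 0, drift = 2.4, noise_sd = 1.2),
      proprio_hand = c(intercept = 2, sway = 0, drift = 1.2, noise_sd = 1.0),
      mri_brainstem = c(intercept = 2, sway = 1.4, drift = 0.5, noise_sd = 0.9),
      mri_cerebellum = c(intercept = 2, sway = 1.2, drift = 0.7, noise_sd = 0.9),
      mri_medulla = c(intercept = 1.5, sway = 1.1, drift = 0.4, noise_sd = 0.8)),
    seed = 1L) {
  if (abs(sum(group_props) - 1) > 1e-8) stop("group proportions must sum to 1")
  stopifnot(all(group_props >= 0), severity_scale > 0)
  if (!all(names(group_props) %in% names(age_range)) ||
      !all(names(group_props) %in% names(group_offsets))) {
    stop("age_range and group_offsets must cover every group")
  }
  structure(list(
    group_props = group_props, age_range = age_range, age_slope = age_slope,
    age_ref = age_ref, group_offsets = group_offsets,
    drift_attenuation = drift_attenuation, severity_scale = severity_scale,
    loadings = loadings, seed = as.integer(seed)
  ), class = "cohort_sim_params")
}

#' Composite score of the sway-relevant examination subpanels
#'
#' The square root of the sum of the stance & gait, lower-extremity
#' cerebellar and lower-extremity proprioceptive panel scores.
#'
#' @param stance_gait,cerebellar,proprioceptive non-negative panel scores
#'   (vectorized).
#' @return composite score(s).
#' @export
neurex_sway_composite <- function(stance_gait, cerebellar, proprioceptive) {
  sqrt(stance_gait + cerebellar + proprioceptive)
}

#' Composite score of the drift-relevant examination subpanels
#'
#' The sum of the per-hand motoric, cerebellar and proprioceptive subsystem
#' scores over both hands.
#'
#' @param ... non-negative per-hand subsystem scores (vectorized).
#' @return composite score(s).
#' @export
neurex_drift_composite <- function(...) {
  Reduce(`+`, list(...))
}

# Vectorized outcome model; exported for clipping/loadings tests.
#' Simulate clinical and imaging outcomes from latent severities
#'
#' @param sev_sway,sev_drift latent severities (log10 amplitude units).
#' @param cohort a [cohort_sim_params()] object.
#' @param seed integer seed for the outcome noise.
#' @return tibble of outcome columns, one row per subject.
#' @export
simulate_outcomes <- function(sev_sway, sev_drift, cohort, seed = 1L) {
  n <- length(sev_sway)
  stopifnot(length(sev_drift) == n)
  zs <- sev_sway / cohort$severity_scale
  zd <- sev_drift / cohort$severity_scale
  lat <- function(name) {
    l <- cohort$loadings[[name]]
    l[["intercept"]] + l[["sway"]] * zs + l[["drift"]] * zd +
      rnorm(n, 0, l[["noise_sd"]])
  }
  withr::with_seed(seed, {
    edss <- clip(round(lat("edss") * 2) / 2, 0, 10)
    combiwise <- clip(lat("combiwise"), 0, 100)
    stance_gait <- pmax(0, lat("stance_gait"))
    cerebellar_le <- pmax(0, lat("cerebellar_le"))
    proprio_le <- pmax(0, lat("proprio_le"))
    motoric_dom <- pmax(0, lat("motoric_hand"))
    motoric_ndom <- pmax(0, lat("motoric_hand"))
    cerebellar_dom <- pmax(0, lat("cerebellar_hand"))
    cerebellar_ndom <- pmax(0, lat("cerebellar_hand"))
    proprio_dom <- pmax(0, lat("proprio_hand"))
    proprio_ndom <- pmax(0, lat("proprio_hand"))
    neurex <- pmax(0, lat("neurex_base")) + stance_gait + cerebellar_le +
      proprio_le + motoric_dom + motoric_ndom + cerebellar_dom +
      cerebellar_ndom + proprio_dom + proprio_ndom
    tibble::tibble(
      edss = edss, combiwise = combiwise, neurex = neurex,
      stance_gait = stance_gait, cerebellar_le = cerebellar_le,
      proprio_le = proprio_le,
      neurex_sway = neurex_sway_composite(stance_gait, cerebellar_le,
                                          proprio_le),
      neurex_drift = neurex_drift_composite(motoric_dom, motoric_ndom,
                                            cerebellar_dom, cerebellar_ndom,
                                            proprio_dom, proprio_ndom),
      neurex_cerebellar_dom = cerebellar_dom,
      mri_brainstem = pmax(0, lat("mri_brainstem")),
      mri_cerebellum = pmax(0, lat("mri_cerebellum")),
      mri_medulla = pmax(0, lat("mri_medulla")))
  })
}

#' Simulate a full cohort: raw traces, cohort table and ground truth
#'
#' Draws diagnosis groups, ages and latent severities; couples clinical and
#' imaging outcomes to the severities via [simulate_outcomes()]; and
#' generates every raw trace (three stance conditions plus two hand
#' conditions per trial) with [simulate_trace()], passing each subject's
#' severity through to the signal amplitude so that downstream biomarkers
#' really carry the designed associations.
#'
#' @param sway a [sway_sim_params()] object.
#' @param cohort a [cohort_sim_params()] object.
#' @param tests which tests to generate traces for.
#' @return a list with elements `traces` (long tibble), `cohort` (one row per
#'   subject) and `truth` (latent severities, variance components, loadings).
#' @export
simulate_cohort <- function(sway, cohort, tests = c("sway", "drift")) {
  stopifnot(inherits(sway, "sway_sim_params"),
            inherits(cohort, "cohort_sim_params"))
  n <- sway$n_subjects
  groups <- names(cohort$group_props)

  subj <- withr::with_seed(derive_seed(cohort$seed, 10L), {
    # deterministic counts by proportion, remainder to the largest fractions
    raw <- cohort$group_props * n
    cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    grp <- sample(rep(groups, cnt))
    age <- vapply(grp, function(g) {
      r <- cohort$age_range[[g]]
      runif(1, r[1], r[2])
    }, numeric(1))
    tibble::tibble(
      subject_id = subject_id_of(seq_len(n)),
      age = round(age, 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      height = round(rnorm(n, ifelse(sex == "M", 177, 164), 7), 1),
      weight = round(rnorm(n, ifelse(sex == "M", 82, 68), 12), 1),
      dominant_hand = sample(c("right", "left"), n, replace = TRUE,
                             prob = c(0.9, 0.1)),
      diagnosis = grp)
  })

  base <- cohort$age_slope * (subj$age - cohort$age_ref)
  offs <- cohort$group_offsets[subj$diagnosis]
  sev <- withr::with_seed(derive_seed(cohort$seed, 11L), {
    list(sway = base + unname(offs) + rnorm(n, 0, sway$between_sd),
         drift = cohort$drift_attenuation * (base + unname(offs)) +
           rnorm(n, 0, sway$between_sd))
  })

  outcomes <- simulate_outcomes(sev$sway, sev$drift, cohort,
                                seed = derive_seed(cohort$seed, 12L))
  cohort_tbl <- dplyr::bind_cols(subj, outcomes)

  conds <- c(if ("sway" %in% tests) sway_conditions,
             if ("drift" %in% tests) drift_conditions)
  grid <- expand.grid(subject = seq_len(n), trial = seq_len(sway$n_trials),
                      condition = conds, stringsAsFactors = FALSE)
  traces <- purrr::pmap(grid, function(subject, trial, condition) {
    s <- if (condition %in% drift_conditions) {
      sev$drift[subject]
    } else {
      sev$sway[subject]
    }
    simulate_trace(sway, subject, trial, condition, severity = s)
  })
  traces <- dplyr::bind_rows(traces)

  list(traces = traces, cohort = cohort_tbl,
       truth = list(severity_sway = sev$sway, severity_drift = sev$drift,
                    between_sd = sway$between_sd, within_sd = sway$within_sd,
                    designed_icc = designed_icc(sway),
                    age_slope = cohort$age_slope,
                    group_offsets = cohort$group_offsets,
                    loadings = cohort$loadings))
}

#' Simulate a biomarker panel with designed per-column reliability
#'
#' Generates panel-shaped data directly from the variance-ratio definition of
#' the ICC: column `j` is `b_i + w_ij` with `var(b) = icc_j * total_sd^2` and
#' `var(w) = (1 - icc_j) * total_sd^2`, so its designed ICC is exactly
#' `icc_j`.  Used to test the reliability screen against ground truth without
#' generating raw signals.
#'
#' @param n_subjects subjects.
#' @param icc vector of designed ICCs, one per biomarker column.
#' @param n_trials trials per subject.
#' @param total_sd total (between + within) standard deviation per column.
#' @param names optional column names (default `B01`, `B02`, ...).
#' @param seed integer seed.
#' @return a wide tibble with `subject_id`, `trial_id` and one column per
#'   designed biomarker.
#' @export
simulate_reliability_panel <- function(n_subjects, icc, n_trials = 2,
                                       total_sd = 1, names = NULL,
                                       seed = 1L) {
  stopifnot(all(icc >= 0 & icc <= 1), n_subjects >= 2, n_trials >= 2)
  p <- length(icc)
  if (is.null(names)) names <- sprintf("B%02d", seq_len(p))
  withr::with_seed(seed, {
    cols <- lapply(seq_len(p), function(j) {
      sb <- total_sd * sqrt(icc[j])
      sw <- total_sd * sqrt(1 - icc[j])
      b <- rnorm(n_subjects, 0, sb)
      as.vector(vapply(seq_len(n_trials),
                       function(t) b + rnorm(n_subjects, 0, sw),
                       numeric(n_subjects)))
    })
  })
  out <- tibble::tibble(
    subject_id = rep(subject_id_of(seq_len(n_subjects)), n_trials),
    trial_id = rep(trial_id_of(seq_len(n_trials)), each = n_subjects))
  for (j in seq_len(p)) out[[names[j]]] <- cols[[j]]
  out
}

#' Simulate feature matrices with independently contributing tests
#'
#' Feature-level generator for modeling experiments: sway features load on a
#' latent sway severity, drift features on an independent drift severity, and
#' the outcome is a linear combination of both plus noise.  Returns the
#' design matrices and the full ground truth.
#'
#' @param n_subjects subjects.
#' @param n_sway,n_drift number of sway / drift features.
#' @param load_sway,load_drift outcome loadings on the two severities.
#' @param feature_noise_sd residual sd of each feature around its loading.
#' @param outcome_noise_sd residual sd of the outcome.
#' @param seed integer seed.
#' @return list with `x_sway`, `x_drift` (matrices), `y` (outcome) and
#'   `truth`.
#' @export
simulate_biomarker_cohort <- function(n_subjects, n_sway = 12, n_drift = 8,
                                      load_sway = 1, load_drift = 1,
                                      feature_noise_sd = 0.6,
                                      outcome_noise_sd = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    s1 <- rnorm(n_subjects)
    s2 <- rnorm(n_subjects)
    a <- runif(n_sway, 0.5, 1)
    b <- runif(n_drift, 0.5, 1)
    x_sway <- vapply(a, function(aj) aj * s1 +
                       rnorm(n_subjects, 0, feature_noise_sd),
                     numeric(n_subjects))
    x_drift <- vapply(b, function(bj) bj * s2 +
                        rnorm(n_subjects, 0, feature_noise_sd),
                      numeric(n_subjects))
    y <- load_sway * s1 + load_drift * s2 + rnorm(n_subjects, 0,
                                                  outcome_noise_sd)
  })
  colnames(x_sway) <- sprintf("sway%02d", seq_len(n_sway))
  colnames(x_drift) <- sprintf("drift%02d", seq_len(n_drift))
  list(x_sway = x_sway, x_drift = x_drift, y = y,
       truth = list(sev_sway = s1, sev_drift = s2,
                    load_sway = load_sway, load_drift = load_drift))
}

#' Write raw traces to the long CSV interchange format
#'
#' Columns: `subject_id, trial_id, test, condition, t_s, ax, ay, az`.
#'
#' @param traces long trace tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces[, c("subject_id", "trial_id", "test", "condition",
                              "t_s", "ax", "ay", "az")], path)
  invisible(path)
}

#' Write a cohort table to CSV
#' @param cohort cohort tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
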