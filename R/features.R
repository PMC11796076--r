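#' Root-mean-square acceleration
#'
#' `sqrt(mean(a^2))` — the amplitude of sway over a test.  For the net axis
#' this is applied to the radial series, which equals
#' `sqrt(mean(aml^2 + aap^2))`.
#'
#' @param x numeric acceleration series, m/s^2.
#' @return RMS, m/s^2.
#' @export
rms <- function(x) {
  if (length(x) < 1) stop("rms: empty series")
  sqrt(mean(x^2))
}

#' Integrated squared jerk
#'
#' Discretization of `integral (dAcc/dt)^2 dt` by forward first differences
#' and the rectangle rule: `sum(((a[i+1] - a[i]) / dt)^2) * dt` with
#' `dt = 1/sample_rate`.  Measures sway jerkiness; invariant to additive
#' constants and quadratic in amplitude.
#'
#' @param x numeric acceleration series, m/s^2.
#' @param sample_rate sampling frequency, Hz.
#' @return integrated squared jerk, (m/s^3)^2 * s.
#' @export
jerk <- function(x, sample_rate) {
  if (length(x) < 2) stop("jerk: need at least 2 samples")
  sum(diff(x)^2) * sample_rate
}

#' Net integrated squared jerk over both horizontal axes
#'
#' Half the sum of the M-L and A-P jerks:
#' `(1/2) * (jerk(aml) + jerk(aap))`.
#'
#' @param aml,aap medio-lateral and antero-posterior series (equal length).
#' @param sample_rate sampling frequency, Hz.
#' @return net jerk.
#' @export
net_jerk <- function(aml, aap, sample_rate) {
  if (length(aml) != length(aap)) stop("net_jerk: length mismatch")
  (jerk(aml, sample_rate) + jerk(aap, sample_rate)) / 2
}

#' One-sided periodogram restricted to an analysis band
#'
#' Discrete Fourier transform of the mean-subtracted series (rectangular
#' window, no segment averaging), scaled to power spectral density so that
#' `sum(s) * df` over the full band equals the series variance (Parseval),
#' then restricted to frequency bins within `band`.
#'
#' @param x numeric series (length >= 8).
#' @param sample_rate sampling frequency, Hz.
#' @param band `c(b1, b2)` band edges in Hz, within `(0, Nyquist]`.
#' @return a tibble with columns `f` (Hz) and `s` (PSD); attribute `band`.
#' @export
power_spectrum <- function(x, sample_rate, band = c(0.15, 10)) {
  n <- length(x)
  if (n < 8) stop("power_spectrum: need at least 8 samples")
  nyq <- sample_rate / 2
  if (band[1] >= band[2] || band[2] > nyq + 1e-12 || band[1] < 0) {
    stop("power_spectrum: band must satisfy 0 <= b1 < b2 <= Nyquist")
  }
  x <- x - mean(x)
  X <- fft(x)
  half <- seq_len(floor(n / 2) + 1)            # k = 0 .. floor(n/2)
  f <- (half - 1) * sample_rate / n
  psd <- Mod(X[half])^2 / (n * sample_rate)
  scale2 <- rep(2, length(half))
  scale2[1] <- 1                                # DC
  if (n %% 2 == 0) scale2[length(half)] <- 1    # Nyquist bin
  psd <- psd * scale2
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) stop("power_spectrum: band empty after restriction")
  out <- tibble::tibble(f = f[keep], s = psd[keep])
  attr(out, "band") <- band
  attr(out, "df") <- sample_rate / n
  out
}

#' Spectral centroid (first spectral moment)
#'
#' PSD-weighted mean frequency over the analysis band:
#' `mu1 = sum(f * s) / sum(s)` — the "center of gravity" of sway frequency.
#'
#' @param spec a [power_spectrum()] tibble.
#' @return centroid in Hz, or `NA` (with attribute `flag = "zero_power"`)
#'   when the in-band power is zero.
#' @export
spectral_centroid <- function(spec) {
  tot <- sum(spec$s)
  if (tot <= 0) {
    return(structure(NA_real_, flag = "zero_power"))
  }
  sum(spec$f * spec$s) / tot
}

#' Spectral spread (second spectral moment)
#'
#' PSD-weighted standard deviation of frequency about the centroid:
#' `mu2 = sqrt(sum((f - mu1)^2 * s) / sum(s))` — dispersion of sway
#' frequency.  Invariant to rescaling the PSD.
#'
#' @param spec a [power_spectrum()] tibble.
#' @return spread in Hz, or `NA` when the in-band power is zero.
#' @export
spectral_spread <- function(spec) {
  tot <- sum(spec$s)
  if (tot <= 0) {
    return(structure(NA_real_, flag = "zero_power"))
  }
  mu1 <- sum(spec$f * spec$s) / tot
  sqrt(sum((spec$f - mu1)^2 * spec$s) / tot)
}

# Features of one calibrated trace, long format.
trace_features <- function(cal, band = c(0.15, 10)) {
  fs <- attr(cal, "sample_rate")
  prov <- attr(cal, "provenance")
  sc_ss <- function(x) {
    spec <- power_spectrum(x, fs, band)
    c(SC = as.numeric(spectral_centroid(spec)),
      SS = as.numeric(spectral_spread(spec)))
  }
  ml <- sc_ss(cal$a_ml); ap <- sc_ss(cal$a_ap); net <- sc_ss(cal$a_net)
  tibble::tibble(
    subject_id = prov$subject_id, trial_id = prov$trial_id,
    test = prov$test, condition = prov$condition,
    measure = rep(c("RMS", "Jerk", "SC", "SS"), each = 3),
    axis = rep(c("ML", "AP", "Net"), 4),
    value = c(rms(cal$a_ml), rms(cal$a_ap), rms(cal$a_net),
              jerk(cal$a_ml, fs), jerk(cal$a_ap, fs),
              net_jerk(cal$a_ml, cal$a_ap, fs),
              ml[["SC"]], ap[["SC"]], net[["SC"]],
              ml[["SS"]], ap[["SS"]], net[["SS"]]))
}

#' Extract the four measurement families from raw traces
#'
#' For every (subject, trial, test, condition) group: trim to the final
#' `target_duration` seconds, calibrate into M-L/A-P/Net series, and compute
#' RMS, Jerk (net jerk for the net axis), spectral centroid and spectral
#' spread on each axis.  Groups too short to trim or calibrate are skipped
#' with a warning.
#'
#' @param traces long trace tibble (from [read_traces()] or
#'   [simulate_cohort()]).
#' @param band spectral analysis band `c(b1, b2)`, Hz.
#' @param target_duration trim target, seconds.
#' @param axis_map passed to [calibrate_trace()].
#' @return long tibble: `subject_id, trial_id, test, condition, measure,
#'   axis, value` (raw scale, not log-transformed).
#' @export
extract_features <- function(traces, band = c(0.15, 10), target_duration = 9,
                             axis_map = c("x", "y")) {
  key <- paste(traces$subject_id, traces$trial_id, traces$test,
               traces$condition, sep = "\r")
  groups <- split(seq_len(nrow(traces)), key)
  skipped <- character(0)
  rows <- lapply(groups, function(idx) {
    tr <- traces[idx, ]
    tr <- tr[order(tr$t_s), ]
    res <- tryCatch(
      trace_features(calibrate_trace(trim_trace(tr, target_duration),
                                     axis_map = axis_map),
                     band = band),
      error = function(e) NULL)
    if (is.null(res)) skipped <<- c(skipped, trace_label(tr))
    res
  })
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " trace(s): ",
            paste(skipped, collapse = "; "))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$subject_id, .data$trial_id,
                 .data$test, .data$condition, .data$measure, .data$axis)
}
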