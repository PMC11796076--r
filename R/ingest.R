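#' Read raw traces from the long CSV interchange format
#'
#' Expects columns `subject_id, trial_id, test, condition, t_s, ax, ay, az`
#' (as written by [write_traces()]; real app exports sharing the schema are
#' read identically).  Rows are sorted by time within each (subject, trial,
#' test, condition) group; groups with non-monotone timestamps are dropped
#' with a warning, and groups whose median sampling interval deviates more
#' than `jitter_tol` from the nominal rate are flagged in the `irregular`
#' attribute.
#'
#' @param path CSV file path.
#' @param nominal_rate nominal sampling frequency, Hz.
#' @param jitter_tol tolerated relative deviation of the median sample
#'   interval from `1/nominal_rate`.
#' @return a long tibble of traces; attribute `irregular` lists flagged
#'   groups.
#' @export
read_traces <- function(path, nominal_rate = 50, jitter_tol = 0.2) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  req <- c("subject_id", "trial_id", "test", "condition", "t_s",
           "ax", "ay", "az")
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0) stop("empty trace file: ", path)
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("trace file missing columns: ", paste(missing, collapse = ", "))
  }
  df <- dplyr::arrange(df[, req], .data$subject_id, .data$trial_id,
                       .data$test, .data$condition, .data$t_s)
  key <- paste(df$subject_id, df$trial_id, df$test, df$condition)
  groups <- split(seq_len(nrow(df)), key)
  bad <- character(0)
  irregular <- character(0)
  keep <- logical(nrow(df))
  for (g in names(groups)) {
    idx <- groups[[g]]
    t <- df$t_s[idx]
    if (length(idx) >= 2 && any(diff(t) <= 0)) {
      bad <- c(bad, g)
      next
    }
    keep[idx] <- TRUE
    if (length(idx) >= 2) {
      dt <- median(diff(t))
      if (abs(dt - 1 / nominal_rate) > jitter_tol / nominal_rate) {
        irregular <- c(irregular, g)
      }
    }
  }
  if (length(bad) > 0) {
    warning("dropped ", length(bad), " group(s) with non-monotone timestamps: ",
            paste(bad, collapse = "; "))
  }
  out <- df[keep, ]
  attr(out, "irregular") <- irregular
  out
}

trace_label <- function(trace) {
  paste(trace$subject_id[1], trace$trial_id[1], trace$test[1],
        trace$condition[1])
}

#' Trim a trace to its final seconds
#'
#' Keeps the last `target_duration` seconds of a single-group trace (the
#' leading surplus, which typically contains the reaction to the start cue,
#' is dropped).  The retained length is `round(target_duration * rate)`
#' samples at the trace's nominal rate.
#'
#' @param trace tibble for a single (subject, trial, test, condition) group.
#' @param target_duration seconds to keep.
#' @param sample_rate sampling rate, Hz; inferred from the median timestep
#'   when `NULL`.
#' @return the trimmed trace.
#' @export
trim_trace <- function(trace, target_duration = 9, sample_rate = NULL) {
  n <- nrow(trace)
  if (n < 2) stop("trace too short to trim: ", trace_label(trace))
  if (is.null(sample_rate)) {
    sample_rate <- round(1 / median(diff(trace$t_s)))
  }
  n_target <- round(target_duration * sample_rate)
  if (n < n_target) {
    stop("trace shorter than ", target_duration, " s: ", trace_label(trace),
         " (", n, " samples, need ", n_target, ")")
  }
  trace[seq(n - n_target + 1, n), ]
}

#' Calibrate a trace into M-L, A-P and Net series
#'
#' Gravity/tilt correction for hand-held or harness-mounted accelerometry:
#' the mean acceleration vector over the trace defines the vertical; the
#' minimal rotation taking that vector to `(0, 0, |mean|)` is applied to
#' every sample; the two horizontal components after rotation are assigned
#' to medio-lateral and antero-posterior by `axis_map` and mean-subtracted;
#' the net (radial) series is `sqrt(aml^2 + aap^2)`.
#'
#' @param trace a trimmed single-group trace tibble.
#' @param axis_map which rotated horizontal axes map to (M-L, A-P); one of
#'   `c("x","y")` (default) or `c("y","x")`, covering both landscape
#'   harness orientations.
#' @return a tibble with columns `t_s, a_ml, a_ap, a_net`; attributes
#'   `sample_rate` and `provenance`.
#' @export
calibrate_trace <- function(trace, axis_map = c("x", "y")) {
  axis_map <- match.arg(paste(axis_map, collapse = ""), c("xy", "yx"))
  m <- c(mean(trace$ax), mean(trace$ay), mean(trace$az))
  if (sqrt(sum(m^2)) < 1) {
    stop("cannot determine vertical: mean acceleration below 1 m/s^2 for ",
         trace_label(trace))
  }
  R <- rotation_to_vertical(m)
  rot <- R %*% rbind(trace$ax, trace$ay, trace$az)
  hx <- rot[1, ]
  hy <- rot[2, ]
  if (axis_map == "xy") {
    aml <- hx - mean(hx); aap <- hy - mean(hy)
  } else {
    aml <- hy - mean(hy); aap <- hx - mean(hx)
  }
  out <- tibble::tibble(t_s = trace$t_s, a_ml = aml, a_ap = aap,
                        a_net = sqrt(aml^2 + aap^2))
  attr(out, "sample_rate") <- round(1 / median(diff(trace$t_s)))
  attr(out, "provenance") <- list(subject_id = trace$subject_id[1],
                                  trial_id = trace$trial_id[1],
                                  test = trace$test[1],
                                  condition = trace$condition[1])
  out
}
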