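panel_measures <- c("RMS", "Jerk", "SC", "SS")
panel_axes <- c("ML", "AP", "Net")
stance_codes <- c("EO-FA" = "EOFA", "EO-FT" = "EOFT", "EC-FT" = "ECFT")
ratio_codes <- c("Romberg", "FTFA")   # EC-FT:EO-FT and EO-FT:EO-FA
drift_roles <- c("Dom", "Ndom", "Sum", "Diff")

#' Canonical postural-sway biomarker names
#'
#' The 60 sway columns follow the grammar `<measure>_<axis>_<condition>`:
#' 4 measures x 3 axes x 3 stances (`EOFA`, `EOFT`, `ECFT`) plus the same
#' 12 measures for the two condition ratios `Romberg` (EC-FT over EO-FT,
#' the effect of removing vision) and `FTFA` (EO-FT over EO-FA, the effect
#' of narrowing the stance).
#'
#' @return character vector of 60 names in canonical order.
#' @export
sway_biomarker_names <- function() {
  as.vector(outer(
    as.vector(outer(panel_measures, panel_axes, paste, sep = "_")),
    c(unname(stance_codes), ratio_codes), paste, sep = "_"))
}

#' Canonical pronator-drift biomarker names
#'
#' The 16 drift columns: 4 measures on the net axis for the dominant hand,
#' non-dominant hand, the across-hand sum and the across-hand difference:
#' `<measure>_Net_<Dom|Ndom|Sum|Diff>`.
#'
#' @return character vector of 16 names in canonical order.
#' @export
drift_biomarker_names <- function() {
  as.vector(outer(paste(panel_measures, "Net", sep = "_"), drift_roles,
                  paste, sep = "_"))
}

log10_or_na <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x > 0
  out[ok] <- log10(x[ok])
  out
}

check_duplicates <- function(features, keys) {
  dup <- duplicated(features[, keys])
  if (any(dup)) {
    stop("duplicate feature entries for: ",
         paste(utils::head(do.call(paste, features[dup, keys]), 5),
               collapse = "; "))
  }
}

complete_columns <- function(panel, biomarkers) {
  for (b in setdiff(biomarkers, names(panel))) panel[[b]] <- NA_real_
  panel[, c("subject_id", "trial_id", biomarkers)]
}

#' Assemble the 60-column postural-sway biomarker panel
#'
#' One row per (subject, trial).  Stance columns are `log10(feature)`;
#' ratio columns are computed on the raw scale and then log-transformed,
#' i.e. `log10(value_A / value_B)`, so a ratio column always equals the
#' difference of its two stance columns.  A cell is missing when the raw
#' feature is missing or non-positive, and a ratio cell whenever either
#' constituent is missing.  All 60 columns are always present.
#'
#' @param features long feature tibble from [extract_features()] (raw
#'   scale); only `test == "sway"` rows are used.
#' @return wide tibble: `subject_id`, `trial_id`, 60 biomarker columns.
#' @export
build_sway_panel <- function(features) {
  sw <- features[features$test == "sway", ]
  check_duplicates(sw, c("subject_id", "trial_id", "condition", "measure",
                         "axis"))
  sw$stance <- unname(stance_codes[sw$condition])
  if (anyNA(sw$stance)) stop("unknown sway condition label")
  sw$name <- paste(sw$measure, sw$axis, sw$stance, sep = "_")
  wide_raw <- tidyr::pivot_wider(
    sw[, c("subject_id", "trial_id", "name", "value")],
    names_from = "name", values_from = "value")

  out <- wide_raw[, c("subject_id", "trial_id")]
  for (m in panel_measures) {
    for (a in panel_axes) {
      base <- paste(m, a, sep = "_")
      get <- function(st) {
        col <- paste(base, st, sep = "_")
        if (col %in% names(wide_raw)) wide_raw[[col]] else
          rep(NA_real_, nrow(wide_raw))
      }
      eofa <- get("EOFA"); eoft <- get("EOFT"); ecft <- get("ECFT")
      out[[paste0(base, "_EOFA")]] <- log10_or_na(eofa)
      out[[paste0(base, "_EOFT")]] <- log10_or_na(eoft)
      out[[paste0(base, "_ECFT")]] <- log10_or_na(ecft)
      out[[paste0(base, "_Romberg")]] <- log10_or_na(ecft / eoft)
      out[[paste0(base, "_FTFA")]] <- log10_or_na(eoft / eofa)
    }
  }
  complete_columns(out, sway_biomarker_names())
}

#' Assemble the 16-column pronator-drift biomarker panel
#'
#' Net-axis features of the left/right hand tests are relabeled dominant
#' (`Dom`) / non-dominant (`Ndom`) from the per-subject hand-dominance
#' declaration.  `Sum` is `log10(dom + ndom)` on the raw scale; `Diff` is
#' `log10(dom) - log10(ndom)` (the log of the raw ratio — the raw
#' difference can be non-positive, so the order-preserving log-ratio is
#' used).  Trials of subjects with no dominance declaration are excluded
#' with a warning.
#'
#' @param features long feature tibble from [extract_features()]; only
#'   `test == "drift"`, `axis == "Net"` rows are used.
#' @param dominance tibble with columns `subject_id` and `dominant_hand`
#'   (`"left"` or `"right"`).
#' @return wide tibble: `subject_id`, `trial_id`, 16 biomarker columns.
#' @export
build_drift_panel <- function(features, dominance) {
  dr <- features[features$test == "drift" & features$axis == "Net", ]
  check_duplicates(dr, c("subject_id", "trial_id", "condition", "measure"))
  if (!all(dr$condition %in% drift_conditions)) {
    stop("unknown hand label in drift features")
  }
  dom <- dominance[, c("subject_id", "dominant_hand")]
  if (!all(dom$dominant_hand %in% drift_conditions)) {
    stop("dominant_hand must be 'left' or 'right'")
  }
  undeclared <- setdiff(unique(dr$subject_id), dom$subject_id)
  if (length(undeclared) > 0) {
    warning("excluding subjects with no hand-dominance declaration: ",
            paste(undeclared, collapse = ", "))
    dr <- dr[!dr$subject_id %in% undeclared, ]
  }
  dr <- dplyr::left_join(dr, dom, by = "subject_id")
  dr$role <- ifelse(dr$condition == dr$dominant_hand, "Dom", "Ndom")
  dr$name <- paste(dr$measure, "Net", dr$role, sep = "_")
  wide_raw <- tidyr::pivot_wider(
    dr[, c("subject_id", "trial_id", "name", "value")],
    names_from = "name", values_from = "value")

  out <- wide_raw[, c("subject_id", "trial_id")]
  for (m in panel_measures) {
    get <- function(role) {
      col <- paste(m, "Net", role, sep = "_")
      if (col %in% names(wide_raw)) wide_raw[[col]] else
        rep(NA_real_, nrow(wide_raw))
    }
    d <- get("Dom"); nd <- get("Ndom")
    out[[paste(m, "Net", "Dom", sep = "_")]] <- log10_or_na(d)
    out[[paste(m, "Net", "Ndom", sep = "_")]] <- log10_or_na(nd)
    out[[paste(m, "Net", "Sum", sep = "_")]] <- log10_or_na(d + nd)
    out[[paste(m, "Net", "Diff", sep = "_")]] <-
      log10_or_na(d) - log10_or_na(nd)
  }
  complete_columns(out, drift_biomarker_names())
}

#' Build the combined 76-column biomarker panel
#'
#' Full outer join of the sway and drift panels on (subject, trial).
#'
#' @param features long feature tibble from [extract_features()].
#' @param dominance per-subject hand dominance (see [build_drift_panel()]).
#' @return wide tibble with `subject_id`, `trial_id` and 76 biomarker
#'   columns.
#' @export
build_panel <- function(features, dominance) {
  sway <- build_sway_panel(features)
  drift <- build_drift_panel(features, dominance)
  out <- dplyr::full_join(sway, drift, by = c("subject_id", "trial_id"))
  complete_columns(out, c(sway_biomarker_names(), drift_biomarker_names()))
}

panel_biomarkers <- function(panel) {
  setdiff(names(panel), c("subject_id", "trial_id"))
}

#' Flag outlier biomarker cells by the interquartile-range fence
#'
#' Per biomarker column, Q1 and Q3 are computed (type-7 linear-interpolation
#' quantiles) on the reference rows (the training subjects, or all rows);
#' cells outside `[Q1 - k*IQR, Q3 + k*IQR]` with `k = fence_multiplier` are
#' flagged.  Values are preserved — downstream stages consult the flags.
#'
#' @param panel wide biomarker panel.
#' @param reference_ids subject ids defining the fence reference set
#'   (default: all subjects).
#' @param fence_multiplier the IQR multiplier `k`.
#' @return a tibble of logical flags (`TRUE` = outlier) with the same id and
#'   biomarker columns as `panel`.
#' @export
flag_outliers <- function(panel, reference_ids = NULL,
                          fence_multiplier = 1.5) {
  biomarkers <- panel_biomarkers(panel)
  ref <- if (is.null(reference_ids)) rep(TRUE, nrow(panel)) else
    panel$subject_id %in% reference_ids
  flags <- panel[, c("subject_id", "trial_id")]
  for (b in biomarkers) {
    x <- panel[[b]]
    xr <- x[ref & !is.na(x)]
    if (length(xr) == 0) {
      warning("all-missing biomarker column (no fences): ", b)
      flags[[b]] <- rep(FALSE, nrow(panel))
      next
    }
    q <- quantile(xr, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    if (iqr == 0) {               # avoids Inf * 0 with an infinite fence
      lo <- q[1]; hi <- q[2]
    } else {
      lo <- q[1] - fence_multiplier * iqr
      hi <- q[2] + fence_multiplier * iqr
    }
    flags[[b]] <- !is.na(x) & (x < lo | x > hi)
  }
  flags
}

#' Set outlier-flagged cells to missing
#'
#' @param panel wide biomarker panel.
#' @param flags flag tibble from [flag_outliers()] (same row order).
#' @return the panel with flagged cells replaced by `NA`.
#' @export
mask_outliers <- function(panel, flags) {
  stopifnot(nrow(panel) == nrow(flags),
            all(panel$subject_id == flags$subject_id),
            all(panel$trial_id == flags$trial_id))
  for (b in intersect(panel_biomarkers(panel), names(flags))) {
    panel[[b]][flags[[b]]] <- NA_real_
  }
  panel
}
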