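# Hand-built long feature tables make panel arithmetic fully predictable.
fake_sway_features <- function(subjects = "S001", trials = "T1",
                               conditions = c("EO-FA", "EO-FT", "EC-FT"),
                               value_fn = function(...) 1) {
  grid <- expand.grid(subject_id = subjects, trial_id = trials,
                      condition = conditions,
                      measure = c("RMS", "Jerk", "SC", "SS"),
                      axis = c("ML", "AP", "Net"),
                      stringsAsFactors = FALSE)
  grid$test <- "sway"
  grid$value <- mapply(value_fn, grid$condition, grid$measure, grid$axis)
  tibble::as_tibble(grid)
}

fake_drift_features <- function(subjects = "S001", trials = "T1",
                                value_fn = function(...) 1) {
  grid <- expand.grid(subject_id = subjects, trial_id = trials,
                      condition = c("left", "right"),
                      measure = c("RMS", "Jerk", "SC", "SS"),
                      axis = "Net", stringsAsFactors = FALSE)
  grid$test <- "drift"
  grid$value <- mapply(value_fn, grid$condition, grid$measure, grid$axis)
  tibble::as_tibble(grid)
}

test_that("a complete trial yields exactly the 60 named sway columns", {
  panel <- build_sway_panel(fake_sway_features(value_fn = function(...)
    runif(1, 1, 2)))
  expect_equal(setdiff(names(panel), c("subject_id", "trial_id")),
               sway_biomarker_names())
  expect_length(sway_biomarker_names(), 60)
  expect_equal(sum(is.na(panel[, -(1:2)])), 0)
})

test_that("identical conditions give zero log-ratio columns", {
  panel <- build_sway_panel(fake_sway_features(value_fn = function(...) 3.7))
  romberg <- grep("_Romberg$", names(panel), value = TRUE)
  ftfa <- grep("_FTFA$", names(panel), value = TRUE)
  expect_length(romberg, 12)
  expect_length(ftfa, 12)
  expect_true(all(abs(as.numeric(panel[1, romberg])) < 1e-12))
  expect_true(all(abs(as.numeric(panel[1, ftfa])) < 1e-12))
})

test_that("missing EO-FA propagates to its stance and ratio columns only", {
  feats <- fake_sway_features(conditions = c("EO-FT", "EC-FT"),
                              value_fn = function(...) 2)
  panel <- build_sway_panel(feats)
  vals <- panel[, sway_biomarker_names()]
  expect_equal(sum(is.na(vals)), 12 + 12)       # EOFA stances + FTFA ratios
  expect_true(all(is.na(vals[, grep("_EOFA$", names(vals))])))
  expect_true(all(is.na(vals[, grep("_FTFA$", names(vals))])))
  expect_false(anyNA(vals[, grep("_Romberg$", names(vals))]))
})

test_that("log-scale ratio identity links stance and ratio columns", {
  set.seed(13)
  panel <- build_sway_panel(fake_sway_features(
    subjects = c("S001", "S002"), trials = c("T1", "T2"),
    value_fn = function(...) runif(1, 0.5, 5)))
  for (m in c("RMS", "Jerk", "SC", "SS")) {
    for (a in c("ML", "AP", "Net")) {
      b <- paste(m, a, sep = "_")
      expect_equal(panel[[paste0(b, "_ECFT")]] - panel[[paste0(b, "_EOFT")]],
                   panel[[paste0(b, "_Romberg")]], tolerance = 1e-12)
      expect_equal(panel[[paste0(b, "_EOFT")]] - panel[[paste0(b, "_EOFA")]],
                   panel[[paste0(b, "_FTFA")]], tolerance = 1e-12)
    }
  }
})

test_that("duplicate feature entries are rejected", {
  feats <- fake_sway_features()
  expect_error(build_sway_panel(rbind(feats, feats[1, ])), "duplicate")
})

test_that("non-positive raw features become missing before the log", {
  feats <- fake_sway_features(value_fn = function(cond, m, a)
    if (m == "SS") 0 else 2)
  panel <- build_sway_panel(feats)
  expect_true(all(is.na(panel[, grep("^SS_", names(panel))])))
  expect_false(anyNA(panel[, grep("^RMS_", names(panel))]))
})

test_that("the drift panel has 16 columns with the stated transforms", {
  dom <- tibble::tibble(subject_id = "S001", dominant_hand = "right")
  feats <- fake_drift_features(value_fn = function(cond, m, a)
    if (cond == "right") 10 else 1)
  panel <- build_drift_panel(feats, dom)
  expect_equal(setdiff(names(panel), c("subject_id", "trial_id")),
               drift_biomarker_names())
  expect_length(drift_biomarker_names(), 16)
  expect_equal(panel$RMS_Net_Dom, 1)                     # log10(10)
  expect_equal(panel$RMS_Net_Ndom, 0)                    # log10(1)
  expect_equal(panel$RMS_Net_Sum, log10(11), tolerance = 1e-12)
  expect_equal(panel$RMS_Net_Diff, 1, tolerance = 1e-12)
})

test_that("identical hands give zero Diff columns", {
  dom <- tibble::tibble(subject_id = "S001", dominant_hand = "left")
  panel <- build_drift_panel(fake_drift_features(value_fn = function(...) 4),
                             dom)
  expect_true(all(abs(as.numeric(
    panel[1, grep("_Diff$", names(panel))])) < 1e-12))
})

test_that("swapping the dominance declaration swaps hands and negates Diff", {
  feats <- fake_drift_features(value_fn = function(cond, m, a)
    runif(1, 1, 3))
  right <- build_drift_panel(feats,
                             tibble::tibble(subject_id = "S001",
                                            dominant_hand = "right"))
  left <- build_drift_panel(feats,
                            tibble::tibble(subject_id = "S001",
                                           dominant_hand = "left"))
  for (m in c("RMS", "Jerk", "SC", "SS")) {
    expect_equal(right[[paste0(m, "_Net_Dom")]],
                 left[[paste0(m, "_Net_Ndom")]])
    expect_equal(right[[paste0(m, "_Net_Diff")]],
                 -left[[paste0(m, "_Net_Diff")]], tolerance = 1e-12)
    expect_equal(right[[paste0(m, "_Net_Sum")]],
                 left[[paste0(m, "_Net_Sum")]])
  }
})

test_that("subjects without a dominance declaration are excluded loudly", {
  feats <- fake_drift_features(subjects = c("S001", "S002"))
  dom <- tibble::tibble(subject_id = "S001", dominant_hand = "right")
  expect_warning(panel <- build_drift_panel(feats, dom), "S002")
  expect_equal(panel$subject_id, "S001")
})

test_that("column counts are conserved regardless of input completeness", {
  dom <- tibble::tibble(subject_id = "S001", dominant_hand = "right")
  feats <- rbind(fake_sway_features(conditions = "EC-FT"),
                 fake_drift_features())
  panel <- build_panel(feats, dom)
  expect_equal(setdiff(names(panel), c("subject_id", "trial_id")),
               c(sway_biomarker_names(), drift_biomarker_names()))
})

test_that("IQR fences flag the documented example and spare constants", {
  panel <- tibble::tibble(subject_id = sprintf("S%03d", 1:5),
                          trial_id = "T1",
                          a = c(1, 2, 3, 4, 100),
                          b = rep(7, 5))
  flags <- flag_outliers(panel)
  expect_equal(flags$a, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flags$b))
  none <- flag_outliers(panel, fence_multiplier = Inf)
  expect_false(any(none$a))
  masked <- mask_outliers(panel, flags)
  expect_true(is.na(masked$a[5]))
  expect_equal(masked$a[1:4], 1:4 + 0)
})

test_that("fences use only the reference rows", {
  panel <- tibble::tibble(subject_id = sprintf("S%03d", 1:6),
                          trial_id = "T1",
                          a = c(1, 2, 3, 4, 3, 100))
  flags <- flag_outliers(panel, reference_ids = sprintf("S%03d", 1:5))
  expect_true(flags$a[6])
  expect_false(any(flags$a[1:5]))
})
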