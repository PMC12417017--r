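test_that("window index ranges cover centered/trailing/leading modes with
           clipping", {
  grid <- build_epoch_grid(0, 30 * 100, 30)
  expect_equal(window_indices(grid, 5, "centered", 11), c(9, 13))
  expect_equal(window_indices(grid, 1, "trailing", 42), c(42, 42))
  expect_equal(window_indices(grid, 5, "centered", 1), c(1, 3))
  expect_equal(window_indices(grid, 20, "trailing", 5), c(1, 5))
  expect_equal(window_indices(grid, 9, "leading", 98), c(98, 100))
})

test_that("feature manifests carry the published cardinalities", {
  expect_equal(nrow(act_manifest()), 370L)
  expect_equal(nrow(hrv_manifest()), 30L)
  expect_equal(nrow(rrv_manifest()), 60L)
  expect_false(anyDuplicated(act_manifest()$name) > 0)
  expect_false(anyDuplicated(rrv_manifest()$name) > 0)
})

test_that("actigraphy features behave on constant and short inputs", {
  counts <- rep(7, 50)
  fm <- extract_act_features(counts)
  expect_equal(ncol(fm$values), 370L)
  expect_equal(nrow(fm$values), 50L)
  expect_true(all(fm$values[, "ACT_mean_c9"] == 7))
  expect_true(all(fm$values[, "ACT_sd_t10"] == 0))
  expect_true(all(fm$values[, "ACT_zerofrac_l5"] == 0))
  expect_true(all(fm$values[, "ACT_rms_t4"] == 7))
  # single-epoch night: every window clips to length 1, degenerate stats 0
  one <- extract_act_features(5)
  expect_equal(dim(one$values), c(1L, 370L))
  expect_true(all(one$values[, grepl("skewness|kurtosis", colnames(one$values))] == 0))
  expect_false(any(is.na(one$values)))
  expect_error(extract_act_features(c(-1, 2)), "non-negative")
})

test_that("windowed statistics are permutation-invariant where required", {
  x <- sleepstager:::with_seed(3, rpois(30, 20))
  stats_of <- function(v) sleepstager:::roll_stats_cpp(v, 1L, length(v))
  a <- stats_of(as.numeric(x))
  b <- stats_of(as.numeric(sample(x)))
  # mean, median, sd, min, max, iqr, skew, kurt, rms, zerofrac all
  # order-free
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("HRV features match hand-computed values on simple series", {
  grid <- build_epoch_grid(0, 30 * 3, 30)
  groups <- list(rep(800, 30), rep(800, 30), rep(800, 30))
  fm <- extract_hrv_features(groups, grid)
  expect_equal(ncol(fm$values), 30L)
  expect_equal(unname(fm$values[2, "HRV_MeanNN"]), 800)
  expect_equal(unname(fm$values[2, "HRV_SDNN"]), 0)
  expect_equal(unname(fm$values[2, "HRV_RMSSD"]), 0)
  expect_equal(unname(fm$values[2, "HRV_SD2SD1"]), 0)  # degenerate rule
  # alternating 790/810: every successive difference is +-20 -> RMSSD 20
  alt <- list(rep(c(790, 810), 15))
  fa <- extract_hrv_features(alt, build_epoch_grid(0, 30, 30))
  expect_equal(unname(fa$values[1, "HRV_RMSSD"]), 20)
  expect_equal(unname(fa$values[1, "HRV_MeanNN"]), 800)
})

test_that("sparse NN windows are flagged, empty ones zeroed", {
  grid <- build_epoch_grid(0, 30 * 3, 30)
  groups <- list(numeric(0), c(800, 820), numeric(0))
  fm <- extract_hrv_features(groups, grid)
  flags <- attr(fm, "low_data")
  expect_true(all(flags))
  expect_equal(unname(fm$values[2, "HRV_MeanNN"]), 810)
})

test_that("breath detection counts peaks of a clean sinusoid", {
  s <- sine_signal(0.25, 60, 32, amp = 0.5, offset = 0.5)
  br <- detect_breaths(s)
  expect_gte(length(br$peak_times), 14)
  expect_lte(length(br$peak_times), 16)
  expect_equal(median(br$bb_intervals), 4, tolerance = 0.05)
  flat <- uniform_signal(rep(0.5, 1000), 32, 0)
  expect_length(detect_breaths(flat)$peak_times, 0)
})

test_that("merged peaks closer than the distance floor collapse to one", {
  t <- seq(0, 10 - 1 / 32, by = 1 / 32)
  v <- 0.2 + 0.7 * exp(-0.5 * ((t - 4) / 0.15)^2) +
       0.8 * exp(-0.5 * ((t - 5) / 0.15)^2)
  br <- detect_breaths(uniform_signal(v, 32, 0))
  expect_length(br$peak_times, 1)
  expect_equal(br$peak_times, 5, tolerance = 0.25)
})

test_that("RRV features cover 60 columns with the zero-fill rule", {
  grid <- build_epoch_grid(0, 30 * 20, 30)
  peaks <- seq(2, 598, by = 4)  # constant 4-s breathing
  br <- structure(list(peak_times = peaks, trough_times = peaks[-1] - 2,
                       bb_intervals = diff(peaks)),
                  class = "breath_events")
  fm <- extract_rrv_features(br, grid)
  expect_equal(ncol(fm$values), 60L)
  mid <- 10
  expect_equal(unname(fm$values[mid, "RRV_MeanBB_5min"]), 4)
  expect_equal(unname(fm$values[mid, "RRV_MedianBB_7min"]), 4)
  expect_equal(unname(fm$values[mid, "RRV_SDBB_9min"]), 0)
  expect_equal(unname(fm$values[mid, "RRV_MCVBB_5min"]), 0)
  expect_false(any(fm$zero_filled[5:15]))
  # two breaths only: zero-filled, flagged
  br2 <- structure(list(peak_times = c(100, 104),
                        trough_times = 102, bb_intervals = 4),
                   class = "breath_events")
  fm2 <- extract_rrv_features(br2, grid)
  expect_true(all(fm2$zero_filled))
  expect_true(all(fm2$values == 0))
})

test_that("MCVBB equals MadBB/MedianBB wherever MedianBB > 0", {
  spec <- tiny_spec(epochs = 60)
  rec <- simulate_recording(spec, 5, "p1")
  br <- detect_breaths(rec$resp)
  fm <- extract_rrv_features(br, rec$grid)
  for (w in c("5min", "7min", "9min")) {
    med <- fm$values[, paste0("RRV_MedianBB_", w)]
    mad_ <- fm$values[, paste0("RRV_MadBB_", w)]
    mcv <- fm$values[, paste0("RRV_MCVBB_", w)]
    sel <- med > 0
    expect_equal(mcv[sel], (mad_ / med)[sel], tolerance = 1e-12)
  }
})

test_that("assembled matrices have the documented widths per combination", {
  spec <- tiny_spec(epochs = 40)
  rec <- simulate_recording(spec, 3, "p1")
  ml <- assemble_features(rec, "act_hrv_rrv", "ml")
  expect_equal(ncol(ml$features$values), 460L)
  expect_equal(length(ml$labels), rec$grid$n_epochs)
  expect_false(any(is.na(ml$features$values)))
  act_only <- assemble_features(rec, "act", "ml")
  expect_equal(ncol(act_only$features$values), 370L)
  dl2 <- assemble_features(rec, "ACT+HRV", "dl")
  expect_equal(ncol(dl2$features$values), 9L)
  dl3 <- assemble_features(rec, "act_hrv_rrv", "dl")
  expect_equal(ncol(dl3$features$values), 13L)
  expect_equal(colnames(dl3$features$values)[1], "ACT_counts")
  rec$resp <- NULL
  expect_error(assemble_features(rec, "act_hrv_rrv", "ml"), "respiration")
  expect_error(assemble_features(rec, "act_hrv_edrrv", "ml"), "EDR")
})

test_that("labels can be requested at any coarser granularity", {
  spec <- tiny_spec(epochs = 40)
  rec <- simulate_recording(spec, 3, "p1")
  out <- assemble_features(rec, "act", "ml", granularity = 2)
  expect_setequal(levels(out$labels), c("WAKE", "SLEEP"))
})

test_that("stage-conditioned feature means follow the expected physiology", {
  spec <- sim_cohort_spec(night_length_epochs = 480, seed = 19)
  rec <- simulate_recording(spec, 19, "p1")
  out <- assemble_features(rec, "act_hrv_rrv", "ml")
  v <- out$features$values
  st <- as.character(out$labels)
  m <- function(col, stage) mean(v[st == stage, col])
  # movement highest in wake
  expect_gt(m("ACT_mean_c19", "WAKE"), m("ACT_mean_c19", "N3"))
  expect_gt(m("ACT_mean_c19", "WAKE"), m("ACT_mean_c19", "N2"))
  # NN intervals longer in NREM than wake
  expect_gt(m("HRV_MeanNN", "N2"), m("HRV_MeanNN", "WAKE"))
  # breathing irregularity higher in wake/REM than deep sleep
  expect_gt(m("RRV_MCVBB_9min", "REM"), m("RRV_MCVBB_9min", "N3"))
  expect_gt(m("RRV_MCVBB_9min", "WAKE"), m("RRV_MCVBB_9min", "N3"))
})
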