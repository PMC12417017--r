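test_that("Markov hypnograms honour the transition structure", {
  spec <- tiny_spec(epochs = 50)
  spec$transition <- diag(5)  # absorbing states
  h <- simulate_hypnogram(spec, 3)
  expect_true(all(h$stages == "WAKE"))
  # same seed -> identical sequences
  d <- tiny_spec(epochs = 200)
  expect_identical(simulate_hypnogram(d, 4)$stages,
                   simulate_hypnogram(d, 4)$stages)
  expect_error(sim_cohort_spec(transition = matrix(1, 5, 5)),
               "row-stochastic")
})

test_that("long-run stage frequencies match the chain's stationary
           distribution", {
  # a realization several times the chain's mixing time (N3 self-
  # transition 0.92 implies dwell times of ~12 epochs)
  spec <- sim_cohort_spec(night_length_epochs = 30000, seed = 6)
  h <- simulate_hypnogram(spec, 6)
  e <- eigen(t(spec$transition))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stat <- v / sum(v)
  emp <- table(factor(h$stages, levels = colnames(spec$transition))) /
    length(h$stages)
  expect_true(all(abs(as.numeric(emp) - stat) < 0.03))
  # defaults keep the stage mix near the nominal overnight proportions
  nominal <- c(WAKE = 0.15, N1 = 0.05, N2 = 0.45, N3 = 0.15, REM = 0.20)
  expect_true(all(abs(stat - nominal) < 0.10))
})

test_that("activity emissions order stages and honour zero inflation", {
  spec <- tiny_spec(epochs = 960)
  h <- simulate_hypnogram(spec, 8)
  a <- simulate_activity(h, spec, 8)
  expect_identical(simulate_activity(h, spec, 8), a)
  expect_gt(mean(a[h$stages == "WAKE"]), mean(a[h$stages == "N3"]))
  spec2 <- tiny_spec(epochs = 50)
  spec2$activity_zero[] <- 1
  h3 <- hypnogram(rep("N3", 50), build_epoch_grid(0, 1500, 30), 5)
  expect_true(all(simulate_activity(h3, spec2, 1) == 0))
})

test_that("respiration jitter separates REM from deep sleep", {
  spec <- tiny_spec(epochs = 200)
  spec$breath_jitter[] <- 0
  h <- hypnogram(rep("N2", 40), build_epoch_grid(0, 1200, 30), 5)
  r <- simulate_respiration(h, spec, 2)
  # zero jitter at 0.23 Hz -> peaks exactly every 1/0.23 s
  expect_lt(max(abs(diff(r$breath_times) - 1 / 0.23)), 1e-9)
  spec2 <- tiny_spec(epochs = 200)
  hr <- hypnogram(rep("REM", 100), build_epoch_grid(0, 3000, 30), 5)
  hn <- hypnogram(rep("N3", 100), build_epoch_grid(0, 3000, 30), 5)
  cv <- function(x) sd(x) / mean(x)
  cv_rem <- cv(diff(simulate_respiration(hr, spec2, 3)$breath_times))
  cv_n3 <- cv(diff(simulate_respiration(hn, spec2, 3)$breath_times))
  expect_gt(cv_rem, cv_n3)
  expect_identical(simulate_respiration(hr, spec2, 5)$signal$values,
                   simulate_respiration(hr, spec2, 5)$signal$values)
})

test_that("RR emissions encode mean ordering and RSA coupling", {
  spec <- tiny_spec(epochs = 40)
  spec$sd_nn_ms[] <- 0; spec$rsa_gain_ms[] <- 0
  spec$mean_nn_ms[] <- 1000
  h <- hypnogram(rep("N2", 40), build_epoch_grid(0, 1200, 30), 5)
  resp <- simulate_respiration(h, spec, 2)
  rr <- simulate_rr(h, resp$signal, spec, 2)
  expect_true(all(abs(rr$rr_ms - 1000) < 1e-9))
  expect_lt(max(abs(diff(rr$beat_times) - 1)), 1e-9)
  # stage-mean ordering recovered from epoch means
  spec2 <- tiny_spec(epochs = 60)
  spec2$rsa_gain_ms[] <- 0
  hw <- hypnogram(rep(c("WAKE", "N3"), each = 30),
                  build_epoch_grid(0, 1800, 30), 5)
  resp2 <- simulate_respiration(hw, spec2, 4)
  rr2 <- simulate_rr(hw, resp2$signal, spec2, 4)
  first_half <- rr2$beat_times < 900
  expect_gt(mean(rr2$rr_ms[!first_half]), mean(rr2$rr_ms[first_half]))
  # RSA: spectral peak of interpolated RR series at the breath rate
  spec3 <- tiny_spec(epochs = 40)
  spec3$sd_nn_ms[] <- 1; spec3$rsa_gain_ms[] <- 40
  spec3$breath_jitter[] <- 0
  rr3 <- simulate_rr(h, resp$signal, spec3, 7)
  t_out <- seq(min(rr3$beat_times), max(rr3$beat_times), by = 0.25)
  v <- approx(rr3$beat_times, rr3$rr_ms, xout = t_out)$y
  f <- dominant_freq(uniform_signal(v - mean(v), 4, 0))
  expect_lt(abs(f - 0.23), 0.02)
})

test_that("ECG synthesis modulates beat amplitudes with respiration", {
  spec <- tiny_spec(epochs = 20)
  t <- seq(0, 300, by = 1 / 32)
  resp <- uniform_signal(0.5 + 0.5 * sin(2 * pi * 0.25 * t), 32, 0)
  beats <- beat_train(300, seed = 2)
  spec$ecg_noise_sd <- 0
  spec$ecg_mod_depth <- 0
  e0 <- simulate_ecg(beats, resp, spec, 3)
  pk <- detect_r_peaks(e0)
  expect_lt(diff(range(pk$r_amplitudes)), 0.02)
  expect_identical(simulate_ecg(beats, resp, spec, 3)$values, e0$values)
  spec$ecg_mod_depth <- 0.3
  e1 <- simulate_ecg(beats, resp, spec, 3)
  pk1 <- detect_r_peaks(e1)
  amp <- uniform_signal(approx(pk1$r_times, pk1$r_amplitudes,
                               xout = t, rule = 2)$y, 32, 0)
  expect_lt(abs(dominant_freq(uniform_signal(amp$values - mean(amp$values),
                                             32, 0)) - 0.25), 0.02)
  expect_error(simulate_ecg(c(-5, 1), resp, spec, 1), "span")
})

test_that("breath and beat detection recover the generator ground truth", {
  spec <- tiny_spec(epochs = 120)
  rec <- simulate_recording(spec, 31, "p1", with_ecg = TRUE)
  br <- detect_breaths(rec$resp)
  hits <- vapply(rec$ground_truth$breath_times,
                 function(b) any(abs(br$peak_times - b) <= 0.5), TRUE)
  expect_gte(mean(hits), 0.95)
  pk <- detect_r_peaks(rec$ecg)
  beat_hits <- vapply(rec$ground_truth$beat_times,
                      function(b) any(abs(pk$r_times - b) <= 0.05), TRUE)
  expect_gte(mean(beat_hits), 0.99)
})

test_that("cohort bundles round-trip through disk", {
  spec <- tiny_spec(n_participants = 3, epochs = 60, seed = 12)
  dir <- withr::local_tempdir()
  simulate_cohort(spec, out_dir = dir)
  dirs <- list.dirs(dir, recursive = FALSE)
  expect_length(dirs, 3)
  rec <- read_recording_bundle(dirs[1])
  expect_s3_class(rec, "aligned_recording")
  expect_gt(rec$grid$n_epochs, 50)
  expect_equal(rec$hypnogram$granularity, 5)
  # reproducibility: the same master seed gives byte-identical bundles
  dir2 <- withr::local_tempdir()
  simulate_cohort(tiny_spec(n_participants = 3, epochs = 60, seed = 12),
                  out_dir = dir2)
  f1 <- file.path(dirs[1], "activity.csv")
  f2 <- file.path(list.dirs(dir2, recursive = FALSE)[1], "activity.csv")
  expect_identical(readLines(f1), readLines(f2))
})
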