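# Synthetic overnight-cohort generator: Markov hypnograms plus
# stage-conditioned activity, respiration, RR-interval and ECG emission
# models, so every pipeline stage (including EDR) is testable without
# restricted polysomnography data.

SIM_STAGES <- c("WAKE", "N1", "N2", "N3", "REM")

default_transition_matrix <- function() {
  m <- rbind(
    WAKE = c(0.880, 0.080, 0.030, 0.000, 0.010),
    N1   = c(0.150, 0.450, 0.350, 0.000, 0.050),
    N2   = c(0.020, 0.020, 0.885, 0.040, 0.035),
    N3   = c(0.005, 0.000, 0.075, 0.920, 0.000),
    REM  = c(0.040, 0.020, 0.050, 0.000, 0.890))
  colnames(m) <- SIM_STAGES
  m
}

#' Specification of a synthetic overnight cohort
#'
#' Bundles every distributional parameter of the generator: the stage
#' transition matrix, stage-conditioned emission parameters for activity
#' (zero-inflated negative binomial), cardiac rhythm (mean NN, NN spread,
#' respiratory-sinus-arrhythmia coupling), respiration (breath rate and
#' breath-to-breath jitter) and ECG synthesis (rate, amplitude-modulation
#' depth, noise), plus the master seed.  Stage-parameter orderings encode
#' the physiology the classifier is expected to exploit: activity highest
#' in wake, NN intervals longest and steadiest in deep NREM, breathing
#' regular in NREM and irregular in REM, ECG beat amplitudes modulated by
#' respiration.
#'
#' @param n_participants Cohort size (default 20).
#' @param night_length_epochs Night length in 30-s epochs (default 960,
#'   an 8-hour night).
#' @param transition 5x5 row-stochastic stage transition matrix.
#' @param activity_mean,activity_size,activity_zero Per-stage negative
#'   binomial mean/dispersion and zero-inflation probability
#'   (order WAKE, N1, N2, N3, REM).
#' @param mean_nn_ms,sd_nn_ms,rsa_gain_ms Per-stage NN mean, spread and
#'   RSA coupling gain in ms.
#' @param breath_rate_hz,breath_jitter Per-stage breath rate and relative
#'   breath-to-breath jitter.
#' @param resp_rate_hz Respiration waveform sampling rate (default 32 Hz).
#' @param ecg_rate_hz ECG sampling rate (default 256 Hz).
#' @param ecg_amplitude,ecg_mod_depth,ecg_noise_sd Base R-peak amplitude,
#'   respiratory amplitude-modulation depth in `[0, 1]`, additive noise SD.
#' @param stage_effects If FALSE, all stage-conditioned parameters collapse
#'   to the N2 values — a null cohort in which stages are unrecoverable.
#' @param seed Master seed; per-participant seeds derive from it.
#' @return A `sim_cohort_spec` object.
#' @export
sim_cohort_spec <- function(n_participants = 20, night_length_epochs = 960,
                            transition = default_transition_matrix(),
                            activity_mean = c(150, 20, 8, 2, 8),
                            activity_size = 1.2,
                            activity_zero = c(0.05, 0.40, 0.60, 0.85, 0.55),
                            mean_nn_ms = c(800, 900, 950, 1000, 850),
                            sd_nn_ms = c(50, 35, 25, 15, 45),
                            rsa_gain_ms = c(10, 25, 35, 40, 15),
                            breath_rate_hz = c(0.27, 0.25, 0.23, 0.21, 0.26),
                            breath_jitter = c(0.12, 0.05, 0.03, 0.02, 0.15),
                            resp_rate_hz = 32, ecg_rate_hz = 256,
                            ecg_amplitude = 1, ecg_mod_depth = 0.3,
                            ecg_noise_sd = 0.02, stage_effects = TRUE,
                            seed = 1) {
  if (!all(dim(transition) == c(5, 5)) ||
      any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stopf("transition must be a 5x5 row-stochastic matrix")
  if (ecg_mod_depth < 0 || ecg_mod_depth > 1)
    stopf("ecg_mod_depth must lie in [0, 1]")
  stopifnot(all(activity_mean > 0), all(mean_nn_ms > 0),
            all(breath_rate_hz > 0), resp_rate_hz > 0, ecg_rate_hz > 0)
  per_stage <- function(v) setNames(rep_len(v, 5), SIM_STAGES)
  spec <- list(n_participants = n_participants,
               night_length_epochs = night_length_epochs,
               transition = transition,
               activity_mean = per_stage(activity_mean),
               activity_size = activity_size,
               activity_zero = per_stage(activity_zero),
               mean_nn_ms = per_stage(mean_nn_ms),
               sd_nn_ms = per_stage(sd_nn_ms),
               rsa_gain_ms = per_stage(rsa_gain_ms),
               breath_rate_hz = per_stage(breath_rate_hz),
               breath_jitter = per_stage(breath_jitter),
               resp_rate_hz = resp_rate_hz, ecg_rate_hz = ecg_rate_hz,
               ecg_amplitude = ecg_amplitude, ecg_mod_depth = ecg_mod_depth,
               ecg_noise_sd = ecg_noise_sd, seed = seed)
  if (!stage_effects) {
    for (f in c("activity_mean", "activity_zero", "mean_nn_ms", "sd_nn_ms",
                "rsa_gain_ms", "breath_rate_hz", "breath_jitter"))
      spec[[f]] <- per_stage(spec[[f]][["N2"]])
  }
  structure(spec, class = "sim_cohort_spec")
}

#' Simulate a 5-class hypnogram
#'
#' First-order Markov chain over the five AASM stages, starting in WAKE;
#' deterministic given the seed.
#'
#' @param spec A `sim_cohort_spec`.
#' @param seed Integer seed.
#' @return A `hypnogram` at granularity 5.
#' @export
simulate_hypnogram <- function(spec, seed = spec$seed) {
  P <- spec$transition
  n <- spec$night_length_epochs
  stages <- with_seed(seed, {
    s <- integer(n)
    s[1] <- 1L  # WAKE
    for (i in seq_len(n - 1))
      s[i + 1] <- sample.int(5L, 1L, prob = P[s[i], ])
    s
  })
  hypnogram(SIM_STAGES[stages], build_epoch_grid(0, 30 * n, 30), 5)
}

#' Simulate per-epoch activity counts
#'
#' Zero-inflated negative binomial with stage-specific mean and
#' zero-inflation: movement is high in wake and nearly absent in deep
#' sleep.
#'
#' @param h A 5-class `hypnogram`.
#' @param spec A `sim_cohort_spec`.
#' @param seed Integer seed.
#' @return Integer vector of counts, one per epoch.
#' @export
simulate_activity <- function(h, spec, seed = spec$seed) {
  stopifnot(h$granularity == 5)
  mu <- spec$activity_mean[h$stages]
  pz <- spec$activity_zero[h$stages]
  with_seed(seed, {
    nz <- rbinom(length(mu), 1, 1 - pz)
    nz * rnbinom(length(mu), size = spec$activity_size, mu = mu)
  })
}

#' Simulate a respiration waveform with ground-truth breath times
#'
#' Breath (inhalation-peak) times are generated breath by breath: each
#' period is the stage's nominal period perturbed by stage-scaled Gaussian
#' jitter (REM jitter far above NREM jitter).  The waveform is a shaped
#' cosine of unit range peaking at the breath times.
#'
#' @param h A 5-class `hypnogram`.
#' @param spec A `sim_cohort_spec`.
#' @param seed Integer seed.
#' @return List with `signal` (a `uniform_signal` in `[0, 1]`) and
#'   `breath_times` (ground truth, seconds).
#' @export
simulate_respiration <- function(h, spec, seed = spec$seed) {
  stopifnot(h$granularity == 5)
  dur <- h$grid$n_epochs * h$grid$epoch_length
  t_end <- h$grid$start_time + dur
  peaks <- with_seed(seed, {
    p <- numeric(0)
    t <- h$grid$start_time
    repeat {
      st <- h$stages[min(h$grid$n_epochs,
                         floor((t - h$grid$start_time) / 30) + 1)]
      period <- (1 / spec$breath_rate_hz[[st]]) *
        max(0.3, 1 + spec$breath_jitter[[st]] * rnorm(1))
      t <- t + period
      if (t >= t_end) break
      p <- c(p, t)
    }
    p
  })
  n_samp <- round(dur * spec$resp_rate_hz)
  tt <- h$grid$start_time + (seq_len(n_samp) - 1) / spec$resp_rate_hz
  # phase between consecutive peaks; edges extend the neighbouring period
  bounds <- c(2 * peaks[1] - peaks[2], peaks,
              2 * peaks[length(peaks)] - peaks[length(peaks) - 1])
  k <- findInterval(tt, bounds)
  k[k < 1] <- 1; k[k >= length(bounds)] <- length(bounds) - 1
  theta <- (tt - bounds[k]) / (bounds[k + 1] - bounds[k])
  v <- 0.5 + 0.5 * cos(2 * pi * theta)
  list(signal = uniform_signal(v, spec$resp_rate_hz, h$grid$start_time),
       breath_times = peaks)
}

#' Simulate RR intervals with respiratory sinus arrhythmia
#'
#' Beats are produced by integrate-and-fire over the instantaneous RR
#' duration: stage mean NN plus stage-scaled Gaussian variability minus
#' the RSA gain times the respiration phase cosine (heart rate rises on
#' inhalation).
#'
#' @param h A 5-class `hypnogram`.
#' @param resp The `uniform_signal` from [simulate_respiration()].
#' @param spec A `sim_cohort_spec`.
#' @param seed Integer seed.
#' @return List with `beat_times` (seconds) and `rr_ms` (one interval per
#'   beat, ending at that beat).
#' @export
simulate_rr <- function(h, resp, spec, seed = spec$seed) {
  stopifnot(h$granularity == 5)
  t_end <- h$grid$start_time + h$grid$n_epochs * h$grid$epoch_length
  with_seed(seed, {
    beats <- numeric(0); rrs <- numeric(0)
    t <- h$grid$start_time
    repeat {
      st <- h$stages[min(h$grid$n_epochs,
                         floor((t - h$grid$start_time) / 30) + 1)]
      ridx <- min(length(resp$values),
                  max(1, round((t - resp$t0) * resp$rate_hz) + 1))
      cos_phase <- 2 * resp$values[ridx] - 1
      rr <- spec$mean_nn_ms[[st]] + spec$sd_nn_ms[[st]] * rnorm(1) -
            spec$rsa_gain_ms[[st]] * cos_phase
      rr <- max(300, rr)
      t <- t + rr / 1000
      if (t >= t_end) break
      beats <- c(beats, t); rrs <- c(rrs, rr)
    }
    list(beat_times = beats, rr_ms = rrs)
  })
}

ecg_template <- function(rate_hz) {
  tt <- seq(-0.06, 0.03, by = 1 / rate_hz)
  list(offsets = round(tt * rate_hz),
       shape = exp(-0.5 * (tt / 0.008)^2) -
               0.3 * exp(-0.5 * ((tt + 0.04) / 0.010)^2))
}

#' Simulate a single-lead ECG with respiratory amplitude modulation
#'
#' A QRS-like template (trough 40 ms before the R-peak) is placed at each
#' beat with peak amplitude `a0 * (1 + m * (resp(t) - 0.5))`, plus white
#' noise — emulating the impedance-driven amplitude modulation that EDR
#' recovers.
#'
#' @param beat_times Beat times in seconds, within the respiration span.
#' @param resp A `uniform_signal` respiration waveform in `[0, 1]`.
#' @param spec A `sim_cohort_spec`.
#' @param seed Integer seed.
#' @return A `uniform_signal` at `spec$ecg_rate_hz`.
#' @export
simulate_ecg <- function(beat_times, resp, spec, seed = spec$seed) {
  rate <- spec$ecg_rate_hz
  span <- signal_span(resp)
  if (length(beat_times) &&
      (min(beat_times) < span[1] - 1e-9 || max(beat_times) > span[2] + 1e-9))
    stopf("beats fall outside the respiration span")
  n <- round((span[2] - span[1]) * rate)
  tpl <- ecg_template(rate)
  with_seed(seed, {
    v <- rnorm(n, 0, spec$ecg_noise_sd)
    ridx <- pmin(length(resp$values),
                 pmax(1, round((beat_times - resp$t0) * resp$rate_hz) + 1))
    amp <- spec$ecg_amplitude *
      (1 + spec$ecg_mod_depth * (resp$values[ridx] - 0.5))
    bidx <- round((beat_times - span[1]) * rate) + 1
    for (i in seq_along(beat_times)) {
      at <- bidx[i] + tpl$offsets
      ok <- at >= 1 & at <= n
      v[at[ok]] <- v[at[ok]] + amp[i] * tpl$shape[ok]
    }
    uniform_signal(v, rate, span[1])
  })
}

#' Simulate one participant's overnight recording
#'
#' Runs the full emission chain (hypnogram, activity, respiration, RR with
#' RSA, optional ECG) and assembles an `aligned_recording` plus the
#' generator's ground truth.
#'
#' @param spec A `sim_cohort_spec`.
#' @param seed Integer seed for this participant.
#' @param participant_id Identifier string.
#' @param with_ecg Whether to synthesize the ECG waveform (needed only for
#'   the EDR path; default FALSE keeps cohorts light).
#' @return A `sim_recording`: fields of an `aligned_recording` plus
#'   `ground_truth` (true stages, breath times, beat times) and the raw
#'   streams.
#' @export
simulate_recording <- function(spec, seed = spec$seed,
                               participant_id = "sim_01", with_ecg = FALSE) {
  h <- simulate_hypnogram(spec, seed)
  act <- simulate_activity(h, spec, derive_seed(seed, 1))
  resp <- simulate_respiration(h, spec, derive_seed(seed, 2))
  rr <- simulate_rr(h, resp$signal, spec, derive_seed(seed, 3))
  ecg <- if (with_ecg)
    simulate_ecg(rr$beat_times, resp$signal, spec, derive_seed(seed, 4))
  else NULL
  activity_df <- data.frame(start_time_s = epoch_starts(h$grid),
                            count = act)
  nn <- clean_rr_intervals(rr$rr_ms, rr$beat_times)
  rec <- align_streams(activity_df, nn, resp = resp$signal, hypno = h,
                       in_bed = NULL, participant_id = participant_id)
  rec$ecg <- ecg
  rec$ground_truth <- list(stages = h$stages,
                           breath_times = resp$breath_times,
                           beat_times = rr$beat_times)
  rec$raw <- list(activity = activity_df, rr = rr, resp = resp$signal)
  class(rec) <- c("sim_recording", class(rec))
  rec
}

#' Simulate a cohort of overnight recordings
#'
#' Per-participant seeds derive deterministically from the master seed, so
#' the same spec reproduces the same cohort.  With `out_dir` the standard
#' recording bundles are written to disk (see [write_recording_bundle()]);
#' otherwise recordings are returned in memory.
#'
#' @param spec A `sim_cohort_spec`.
#' @param out_dir Optional directory for on-disk bundles.
#' @param with_ecg Whether to synthesize ECG waveforms.
#' @return Named list of `sim_recording`s (invisible when writing to disk).
#' @export
simulate_cohort <- function(spec, out_dir = NULL, with_ecg = FALSE) {
  ids <- sprintf("sim_%02d", seq_len(spec$n_participants))
  recs <- lapply(seq_along(ids), function(i) {
    simulate_recording(spec, derive_seed(spec$seed, 100 + i), ids[i],
                       with_ecg = with_ecg)
  })
  names(recs) <- ids
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids)
      write_recording_bundle(recs[[id]], file.path(out_dir, id))
    return(invisible(recs))
  }
  recs
}
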