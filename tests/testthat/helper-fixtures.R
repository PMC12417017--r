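# Shared in-code fixtures: small synthetic recordings and signals.

tiny_spec <- function(n_participants = 4, epochs = 120, seed = 1, ...) {
  sim_cohort_spec(n_participants = n_participants,
                  night_length_epochs = epochs, seed = seed, ...)
}

# pure sine respiration-like signal
sine_signal <- function(freq_hz, dur_s, rate_hz, amp = 1, offset = 0) {
  t <- seq(0, dur_s - 1 / rate_hz, by = 1 / rate_hz)
  uniform_signal(offset + amp * sin(2 * pi * freq_hz * t), rate_hz, 0)
}

dominant_freq <- function(x) {
  sp <- stats::spec.pgram(stats::ts(x$values, frequency = x$rate_hz),
                          plot = FALSE, taper = 0, detrend = TRUE)
  sp$freq[which.max(sp$spec)]
}

# regular beat train with mild jitter, for EDR fixtures
beat_train <- function(dur_s, mean_rr = 0.82, jitter = 0.04, seed = 1) {
  rr <- sleepstager:::with_seed(seed,
    mean_rr + jitter * (stats::runif(ceiling(dur_s / mean_rr) + 10) - 0.5))
  bt <- cumsum(rr)
  bt[bt < dur_s]
}

amplitude_modulated_ecg <- function(f_mod, dur_s = 300, depth = 0.3,
                                    seed = 1, spec = NULL) {
  if (is.null(spec)) spec <- sim_cohort_spec(ecg_mod_depth = depth)
  t <- seq(0, dur_s, by = 1 / 32)
  resp <- uniform_signal(0.5 + 0.5 * sin(2 * pi * f_mod * t), 32, 0)
  beats <- beat_train(dur_s, seed = seed)
  list(ecg = simulate_ecg(beats, resp, spec, seed), beats = beats,
       resp = resp)
}
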