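# Cleaning of RR-interval series into NN series and the respiration
# waveform chain: band-pass, baseline removal, resampling, normalization.

#' Clean an RR-interval series into NN intervals
#'
#' Three cleaning steps: intervals outside physiological bounds are treated
#' as outliers; intervals whose relative change from the previous kept
#' interval exceeds `ectopic_rel` are treated as ectopic (the 20% rule of
#' Malik); removed positions are linearly interpolated from neighbouring
#' kept intervals and flagged.  Output length equals input length.
#'
#' @param rr_ms RR intervals in milliseconds.
#' @param beat_times Beat times in seconds (ending beat of each interval),
#'   strictly increasing, same length as `rr_ms`.
#' @param low_ms,high_ms Physiological bounds in ms (defaults 300, 2000).
#' @param ectopic_rel Relative-change threshold for ectopy (default 0.2).
#' @return An `nn_series`: `beat_times`, `nn_ms`, and per-interval
#'   `quality_flags` in {"kept", "interpolated"}.
#' @export
clean_rr_intervals <- function(rr_ms, beat_times = NULL, low_ms = 300,
                               high_ms = 2000, ectopic_rel = 0.2) {
  n <- length(rr_ms)
  if (is.null(beat_times)) beat_times <- cumsum(rr_ms) / 1000
  stopifnot(length(beat_times) == n)
  keep <- rr_ms >= low_ms & rr_ms <= high_ms & is.finite(rr_ms)
  if (sum(keep) < 3)
    stopf("fewer than 3 valid NN intervals remain after cleaning")
  prev <- NA_real_
  for (i in seq_len(n)) {
    if (!keep[i]) next
    if (!is.na(prev) && abs(rr_ms[i] - prev) / prev > ectopic_rel) {
      keep[i] <- FALSE
    } else {
      prev <- rr_ms[i]
    }
  }
  if (sum(keep) < 2)
    stopf("fewer than 3 valid NN intervals remain after cleaning")
  nn <- rr_ms
  if (any(!keep)) {
    nn[!keep] <- approx(which(keep), rr_ms[keep], xout = which(!keep),
                        rule = 2)$y
  }
  structure(list(beat_times = beat_times, nn_ms = nn,
                 quality_flags = ifelse(keep, "kept", "interpolated")),
            class = "nn_series")
}

#' Group NN intervals into 30-second epochs
#'
#' Each interval is assigned to the epoch containing its ending beat time
#' (half-open epoch intervals); epochs without beats get empty groups.
#'
#' @param nn An `nn_series`.
#' @param grid An `epoch_grid` sharing the recording time origin.
#' @return List of numeric vectors, one per epoch.
#' @export
epoch_nn <- function(nn, grid) {
  group_by_epoch(nn$beat_times, nn$nn_ms, grid)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given order and applies it
#' forward--backward (zero phase), so breath timings are not shifted.
#'
#' @param x A `uniform_signal`.
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high < rate/2`.
#' @param order Filter order (default 2).
#' @return Filtered `uniform_signal` at the same rate.
#' @export
bandpass_butterworth <- function(x, low_hz, high_hz, order = 2) {
  stopifnot(inherits(x, "uniform_signal"))
  nyq <- x$rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stopf("band [%s, %s] Hz invalid for Nyquist %s Hz", low_hz, high_hz, nyq)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  # center first: the band-pass rejects DC anyway, and filtering the
  # centered signal avoids long start-up transients on offset signals
  mu <- mean(x$values)
  uniform_signal(signal::filtfilt(bf, x$values - mu), x$rate_hz, x$t0)
}

#' Remove slow baseline drift
#'
#' Estimates the baseline as a zero-phase low-pass trend (cutoff
#' `cutoff_hz`, default 0.05 Hz, below the respiration band) and subtracts
#' it.
#'
#' @param x A `uniform_signal`.
#' @param cutoff_hz Trend cutoff in Hz.
#' @return Detrended `uniform_signal`.
#' @export
remove_baseline <- function(x, cutoff_hz = 0.05) {
  stopifnot(inherits(x, "uniform_signal"))
  bf <- signal::butter(2, cutoff_hz / (x$rate_hz / 2), type = "low")
  mu <- mean(x$values)
  trend <- mu + signal::filtfilt(bf, x$values - mu)
  uniform_signal(x$values - trend, x$rate_hz, x$t0)
}

# shared resampler: anti-aliased for decimation, interpolation for the
# EDR upsampling path
resample_signal <- function(x, target_hz, allow_upsample = FALSE) {
  if (target_hz == x$rate_hz) return(x)
  if (target_hz > x$rate_hz && !allow_upsample)
    stopf("target rate %s Hz exceeds input rate %s Hz", target_hz, x$rate_hz)
  v <- x$values
  if (target_hz < x$rate_hz) {
    bf <- signal::butter(4, 0.9 * target_hz / x$rate_hz, type = "low")
    v <- signal::filtfilt(bf, v)
  }
  t_in <- (seq_along(v) - 1) / x$rate_hz
  n_out <- floor(length(v) * target_hz / x$rate_hz)
  t_out <- (seq_len(n_out) - 1) / target_hz
  uniform_signal(approx(t_in, v, xout = t_out, rule = 2)$y, target_hz, x$t0)
}

#' Downsample a uniform signal with anti-alias filtering
#'
#' Low-pass filters below the new Nyquist frequency (zero phase) before
#' resampling; duration is preserved within one sample.  Requesting the
#' input rate is the identity; upsampling is rejected.
#'
#' @param x A `uniform_signal`.
#' @param target_hz Target rate in Hz, `<= rate_hz`.
#' @return Resampled `uniform_signal`.
#' @export
downsample <- function(x, target_hz) {
  stopifnot(inherits(x, "uniform_signal"))
  resample_signal(x, target_hz, allow_upsample = FALSE)
}

#' Min--max normalization to the unit interval
#'
#' Order-preserving affine map `(x - min) / (max - min)`; a constant signal
#' has zero range and is rejected as degenerate.
#'
#' @param x A `uniform_signal`.
#' @return Normalized `uniform_signal` with min 0 and max 1.
#' @export
minmax_normalize <- function(x) {
  stopifnot(inherits(x, "uniform_signal"))
  r <- range(x$values)
  # tolerance-based: a numerically constant signal (e.g. a filtered
  # constant) is as degenerate as an exactly constant one
  if (r[2] - r[1] <= 1e-9 * max(abs(r), 1))
    stopf("constant signal has zero range; cannot normalize")
  uniform_signal((x$values - r[1]) / (r[2] - r[1]), x$rate_hz, x$t0)
}

#' Full respiration preprocessing chain
#'
#' Band-pass (0.1--0.35 Hz, order 2), baseline-drift removal, resampling to
#' `target_hz` (default 32 Hz), then min--max normalization to the unit
#' interval.
#'
#' @param raw A `uniform_signal` respiration (belt or EDR) waveform whose
#'   rate is at least twice the upper band edge.
#' @param low_hz,high_hz Respiration band in Hz.
#' @param target_hz Output rate in Hz.
#' @return Preprocessed `uniform_signal` in `[0, 1]` at `target_hz`.
#' @export
preprocess_respiration <- function(raw, low_hz = 0.1, high_hz = 0.35,
                                   target_hz = 32) {
  x <- bandpass_butterworth(raw, low_hz, high_hz, order = 2)
  x <- remove_baseline(x)
  x <- resample_signal(x, target_hz, allow_upsample = TRUE)
  minmax_normalize(x)
}
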