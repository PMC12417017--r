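# ECG-derived respiration: R-peak and trough detection, per-beat amplitude
# measure, and conversion to a uniform waveform comparable to a belt signal.

#' Detect R-peaks in a single-lead ECG
#'
#' Local maxima above an adaptive amplitude threshold with an enforced
#' refractory period.  When external beat annotations are available they
#' should be supplied directly to [detect_troughs()] / [extract_edr()];
#' this detector is for recordings without annotations.
#'
#' @param ecg A `uniform_signal` at `rate_hz >= 100`.
#' @param refractory_s Minimum inter-beat distance in seconds (default
#'   0.25 s, the physiological QRS refractory bound).
#' @param threshold_frac Fraction of the 99th amplitude percentile used as
#'   the detection threshold.
#' @return List with `r_times` (seconds) and `r_amplitudes`.
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.25, threshold_frac = 0.5) {
  stopifnot(inherits(ecg, "uniform_signal"))
  if (ecg$rate_hz < 100) stopf("ECG rate %s Hz too low for R-peak detection",
                               ecg$rate_hz)
  v <- ecg$values - median(ecg$values)
  q <- quantile(v, 0.999, names = FALSE)
  if (q <= 0) q <- max(v)
  thr <- threshold_frac * q
  if (!is.finite(thr) || thr <= 0 || max(v) <= 0)
    stopf("no R-peaks found: flat or non-positive ECG")
  pk <- pracma::findpeaks(v, minpeakheight = thr,
                          minpeakdistance = max(1, round(refractory_s * ecg$rate_hz)))
  if (is.null(pk) || nrow(pk) == 0) stopf("no R-peaks found above threshold")
  ord <- order(pk[, 2])
  idx <- pk[ord, 2]
  list(r_times = ecg$t0 + (idx - 1) / ecg$rate_hz,
       r_amplitudes = ecg$values[idx])
}

#' Find the trough preceding each R-peak
#'
#' For each R-peak, the minimum sample in the window `[r - window_s, r)`;
#' beats too close to the signal start to carry a full window are dropped
#' (with a count of dropped beats attached).
#'
#' @param ecg A `uniform_signal`.
#' @param r_times R-peak times in seconds, within the signal span.
#' @param window_s Search window before the peak (default 0.1 s, a
#'   physiological QRS bound).
#' @return A `beat_annotations` object: `r_times`, `r_amplitudes`,
#'   `trough_times`, `trough_amplitudes`, attribute `n_dropped`.
#' @export
detect_troughs <- function(ecg, r_times, window_s = 0.1) {
  stopifnot(inherits(ecg, "uniform_signal"))
  r_idx <- round((r_times - ecg$t0) * ecg$rate_hz) + 1
  w <- max(1, round(window_s * ecg$rate_hz))
  ok <- r_idx - w >= 1 & r_idx <= length(ecg$values)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warning(sprintf("%d beat(s) dropped: trough window underflows signal",
                    n_dropped), call. = FALSE)
  r_idx <- r_idx[ok]
  tr_idx <- vapply(r_idx, function(i) {
    win <- (i - w):(i - 1)
    win[which.min(ecg$values[win])]
  }, 0L)
  structure(list(r_times = ecg$t0 + (r_idx - 1) / ecg$rate_hz,
                 r_amplitudes = ecg$values[r_idx],
                 trough_times = ecg$t0 + (tr_idx - 1) / ecg$rate_hz,
                 trough_amplitudes = ecg$values[tr_idx]),
            class = "beat_annotations", n_dropped = n_dropped)
}

#' Per-beat EDR amplitude measure
#'
#' The default measure is the mean of the R-peak amplitude and the
#' preceding trough amplitude per beat; the R-minus-trough difference is a
#' selectable alternative (both appear in the EDR literature).  The series
#' is sampled at the R-peak times; its respiratory modulation becomes the
#' EDR waveform after interpolation and cleaning.
#'
#' @param beats A `beat_annotations` object.
#' @param method "mean" (default) or "difference".
#' @return An `edr_series`: `sample_times` (seconds) and `values`.
#' @export
extract_edr <- function(beats, method = c("mean", "difference")) {
  stopifnot(inherits(beats, "beat_annotations"))
  method <- match.arg(method)
  if (length(beats$r_times) == 0) stopf("no beats to extract EDR from")
  v <- if (method == "mean") (beats$r_amplitudes + beats$trough_amplitudes) / 2
       else beats$r_amplitudes - beats$trough_amplitudes
  structure(list(sample_times = beats$r_times, values = v),
            class = "edr_series")
}

#' Convert a beat-sampled EDR series to a uniform respiration waveform
#'
#' Cubic interpolation of the beat-sampled values onto a uniform
#' intermediate grid (4 Hz, comfortably above twice the 0.35 Hz band top),
#' followed by the same cleaning chain as the belt respiration signal:
#' band-pass 0.1--0.35 Hz, baseline removal, resampling to `target_hz` and
#' min--max normalization.
#'
#' @param edr An `edr_series` with at least 4 beats.
#' @param target_hz Output rate in Hz (default 32).
#' @param interp_hz Intermediate uniform rate in Hz (default 4).
#' @return A `uniform_signal` in `[0, 1]` at `target_hz`.
#' @export
edr_to_signal <- function(edr, target_hz = 32, interp_hz = 4) {
  stopifnot(inherits(edr, "edr_series"))
  if (length(edr$sample_times) < 4)
    stopf("need at least 4 beats to reconstruct an EDR waveform")
  t0 <- edr$sample_times[1]
  t1 <- edr$sample_times[length(edr$sample_times)]
  t_out <- seq(t0, t1, by = 1 / interp_hz)
  v <- spline(edr$sample_times, edr$values, xout = t_out, method = "fmm")$y
  x <- uniform_signal(v, interp_hz, t0)
  preprocess_respiration(x, target_hz = target_hz)
}
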