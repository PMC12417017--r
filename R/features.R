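# Window-wise feature extraction: actigraphy (370), HRV (30) and
# respiratory rate variability (60 = 20 metrics x {5,7,9}-min windows),
# plus assembly of modality-combination feature matrices aligned to labels.

ACT_STATS <- c("mean", "median", "sd", "min", "max", "iqr",
               "skewness", "kurtosis", "rms", "zerofrac")

act_window_configs <- function() {
  rbind(
    data.frame(mode = "centered", length = seq(3, 19, by = 2)),
    data.frame(mode = "trailing", length = 1:20),
    data.frame(mode = "leading", length = 2:9))
}

#' Actigraphy feature manifest
#'
#' 10 summary statistics (mean, median, standard deviation, minimum,
#' maximum, interquartile range, skewness, kurtosis, root-mean-square,
#' fraction of zero-count epochs) over 37 sliding-window configurations
#' (centered lengths 3--19 epochs odd, trailing 1--20, leading 2--9),
#' spanning 30 seconds to 10 minutes: 370 columns.
#'
#' @return Data frame with columns `name`, `modality`, `statistic`,
#'   `window_length_epochs`, `window_mode`.
#' @export
act_manifest <- function() {
  cfg <- act_window_configs()
  out <- do.call(rbind, lapply(seq_len(nrow(cfg)), function(i) {
    data.frame(
      name = sprintf("ACT_%s_%s%d", ACT_STATS,
                     substr(cfg$mode[i], 1, 1), cfg$length[i]),
      modality = "ACT", statistic = ACT_STATS,
      window_length_epochs = cfg$length[i], window_mode = cfg$mode[i])
  }))
  rownames(out) <- NULL
  out
}

HRV_NAMES <- c("MeanNN", "MedianNN", "SDNN", "RMSSD", "SDSD", "CVNN",
               "CVSD", "pNN20", "pNN50", "MadNN", "MCVNN", "IQRNN",
               "VLF", "LF", "HF", "TP", "LFHF", "LFn", "HFn", "LnHF",
               "SD1", "SD2", "SD2SD1", "S", "CSI", "CVI",
               "SampEn", "ApEn", "HTI", "TINN")

#' HRV feature manifest
#'
#' 30 heart-rate-variability features per epoch, computed on NN intervals
#' inside a centered 5-minute (11-epoch) window: 12 time-domain, 8
#' frequency-domain (Welch-style periodogram of the 4 Hz-interpolated NN
#' series; VLF 0.0033--0.04, LF 0.04--0.15, HF 0.15--0.4 Hz) and 10
#' nonlinear (Poincare, entropy, geometric) features.
#'
#' @param window_epochs Centered window length in epochs (default 11).
#' @return Data frame as in [act_manifest()].
#' @export
hrv_manifest <- function(window_epochs = 11) {
  data.frame(name = paste0("HRV_", HRV_NAMES), modality = "HRV",
             statistic = HRV_NAMES, window_length_epochs = window_epochs,
             window_mode = "centered")
}

RRV_NAMES <- c("MeanBB", "MedianBB", "SDBB", "RMSSD", "SDSD", "CVBB",
               "CVSD", "MadBB", "MCVBB", "VLF", "LF", "HF", "LFHF",
               "LFn", "HFn", "SD1", "SD2", "SD2SD1", "ApEn", "SampEn")

#' Respiratory rate variability feature manifest
#'
#' 20 breath-to-breath (BB) interval metrics, each over centered sliding
#' windows of 5, 7 and 9 minutes (suffixes `_5min`/`_7min`/`_9min`): 60
#' columns.  `MCVBB = MadBB / MedianBB` normalizes absolute variability by
#' the median breath interval.
#'
#' @param modality "RRV" (belt) or "EDRRV" (ECG-derived).
#' @param window_minutes Window lengths in minutes.
#' @return Data frame as in [act_manifest()].
#' @export
rrv_manifest <- function(modality = "RRV", window_minutes = c(5, 7, 9)) {
  out <- do.call(rbind, lapply(window_minutes, function(w) {
    data.frame(name = sprintf("%s_%s_%dmin", modality, RRV_NAMES, w),
               modality = modality, statistic = RRV_NAMES,
               window_length_epochs = w * 2, window_mode = "centered")
  }))
  rownames(out) <- NULL
  out
}

DL_HRV_NAMES <- c("MeanNN", "SDNN", "SDSD", "VLF", "HF", "LF", "LFHF", "TP")
DL_RRV_NAMES <- c("MeanBB_5min", "LF_5min", "HF_5min", "LFHF_5min")

#' Reduced input manifest for sequence (deep-learning-style) models
#'
#' Raw activity counts (1 column), eight basic HRV features (MeanNN, SDNN,
#' SDSD, VLF, HF, LF, LF/HF ratio, total power), and four simple RRV or
#' ED-RRV features (MeanBB, LF, HF, LF/HF over the 5-minute window).
#'
#' @param combo Modality combination, e.g. "act_hrv_rrv".
#' @return Character vector of column names selected from the full
#'   feature matrix (plus the raw-counts column).
#' @export
dl_input_names <- function(combo) {
  combo <- normalize_combo(combo)
  nm <- "ACT_counts"
  if (combo != "act") nm <- c(nm, paste0("HRV_", DL_HRV_NAMES))
  if (combo == "act_hrv_rrv") nm <- c(nm, paste0("RRV_", DL_RRV_NAMES))
  if (combo == "act_hrv_edrrv") nm <- c(nm, paste0("EDRRV_", DL_RRV_NAMES))
  nm
}

normalize_combo <- function(combo) {
  c2 <- gsub("[+ ]", "_", tolower(combo))
  c2 <- gsub("_+", "_", c2)
  if (c2 == "ed_rrv") c2 <- "edrrv"
  c2 <- sub("ed_rrv$", "edrrv", c2)
  if (!c2 %in% c("act", "act_hrv", "act_hrv_rrv", "act_hrv_edrrv"))
    stopf("unknown modality combination '%s'", combo)
  c2
}

#' Window index range around an epoch
#'
#' Centered windows of odd length L cover `[i - (L-1)/2, i + (L-1)/2]`;
#' trailing windows `[i - L + 1, i]`; leading windows `[i, i + L - 1]`.
#' Ranges are clipped to the grid, so truncated edge windows are computed
#' on the available epochs.  Epoch indices are 1-based.
#'
#' @param grid An `epoch_grid`.
#' @param length_epochs Window length L in epochs (>= 1).
#' @param mode "centered", "trailing" or "leading".
#' @param epoch 1-based epoch index.
#' @return Integer vector `c(first, last)` of the clipped window.
#' @export
window_indices <- function(grid, length_epochs, mode, epoch) {
  stopifnot(length_epochs >= 1)
  half <- floor(length_epochs / 2)
  r <- switch(mode,
              centered = c(epoch - half, epoch + half),
              trailing = c(epoch - length_epochs + 1, epoch),
              leading = c(epoch, epoch + length_epochs - 1),
              stopf("unknown window mode '%s'", mode))
  c(max(1L, r[1]), min(grid$n_epochs, r[2]))
}

new_feature_matrix <- function(values, manifest, grid, participant_id,
                               zero_filled = NULL) {
  colnames(values) <- manifest$name
  if (is.null(zero_filled)) zero_filled <- rep(FALSE, nrow(values))
  structure(list(participant_id = participant_id, grid = grid,
                 manifest = manifest, values = values,
                 zero_filled = zero_filled),
            class = "feature_matrix")
}

#' Extract the 370 actigraphy features
#'
#' Applies every statistic/window pair of [act_manifest()] to the per-epoch
#' activity counts.  Degenerate windows (too short for skewness/kurtosis,
#' zero variance) emit 0 so matrices stay model-ready.
#'
#' @param activity Non-negative per-epoch activity counts.
#' @param grid An `epoch_grid` with `n_epochs == length(activity)`.
#' @param participant_id Identifier carried into the result.
#' @return A `feature_matrix` with 370 columns.
#' @export
extract_act_features <- function(activity, grid = NULL,
                                 participant_id = "unknown") {
  if (is.null(grid)) grid <- build_epoch_grid(0, 30 * length(activity), 30)
  stopifnot(grid$n_epochs == length(activity))
  if (any(activity < 0)) stopf("activity counts must be non-negative")
  cfg <- act_window_configs()
  n <- grid$n_epochs
  i <- seq_len(n)
  blocks <- lapply(seq_len(nrow(cfg)), function(k) {
    L <- cfg$length[k]
    half <- floor(L / 2)
    r <- switch(cfg$mode[k],
                centered = cbind(i - half, i + half),
                trailing = cbind(i - L + 1, i),
                leading = cbind(i, i + L - 1))
    roll_stats_cpp(as.numeric(activity),
                   pmax(1L, as.integer(r[, 1])),
                   pmin(n, as.integer(r[, 2])))
  })
  new_feature_matrix(do.call(cbind, blocks), act_manifest(), grid,
                     participant_id)
}

# periodogram band powers of an unevenly sampled interval series:
# linear interpolation onto a uniform grid, mean removal, FFT periodogram,
# rectangle-rule integration over each band.
band_powers <- function(times, values, bands, interp_hz) {
  if (length(values) < 4 || diff(range(times)) < 4 / interp_hz)
    return(rep(0, length(bands)))
  t_out <- seq(min(times), max(times), by = 1 / interp_hz)
  if (length(t_out) < 8) return(rep(0, length(bands)))
  v <- approx(times, values, xout = t_out, rule = 2)$y
  v <- v - mean(v)
  n <- length(v)
  P <- Mod(fft(v))^2 / (n * interp_hz)   # two-sided density
  freq <- (seq_len(n) - 1) * interp_hz / n
  half <- seq_len(floor(n / 2) + 1)
  df <- interp_hz / n
  vapply(bands, function(b) {
    sel <- half[freq[half] >= b[1] & freq[half] < b[2]]
    2 * sum(P[sel]) * df
  }, 0)
}

hrv_window_features <- function(nn, low_n_flag = 8) {
  out <- setNames(numeric(30), HRV_NAMES)
  n <- length(nn)
  if (n < 2) return(out)
  dnn <- diff(nn)
  m <- mean(nn); md <- median(nn)
  sdnn <- sd(nn)
  rmssd <- sqrt(mean(dnn^2))
  sdsd <- if (length(dnn) > 1) sd(dnn) else 0
  madnn <- median(abs(nn - md)) * 1.4826
  out["MeanNN"] <- m; out["MedianNN"] <- md; out["SDNN"] <- sdnn
  out["RMSSD"] <- rmssd; out["SDSD"] <- sdsd
  out["CVNN"] <- if (m > 0) sdnn / m else 0
  out["CVSD"] <- if (m > 0) rmssd / m else 0
  out["pNN20"] <- 100 * mean(abs(dnn) > 20)
  out["pNN50"] <- 100 * mean(abs(dnn) > 50)
  out["MadNN"] <- madnn
  out["MCVNN"] <- if (md > 0) madnn / md else 0
  out["IQRNN"] <- quantile(nn, 0.75, names = FALSE) -
                  quantile(nn, 0.25, names = FALSE)
  bp <- band_powers(cumsum(nn) / 1000, nn,
                    list(c(0.0033, 0.04), c(0.04, 0.15), c(0.15, 0.4)),
                    interp_hz = 4)
  tp <- sum(bp)
  out["VLF"] <- bp[1]; out["LF"] <- bp[2]; out["HF"] <- bp[3]
  out["TP"] <- tp
  out["LFHF"] <- if (bp[3] > 0) bp[2] / bp[3] else 0
  out["LFn"] <- if (bp[2] + bp[3] > 0) bp[2] / (bp[2] + bp[3]) else 0
  out["HFn"] <- if (bp[2] + bp[3] > 0) bp[3] / (bp[2] + bp[3]) else 0
  out["LnHF"] <- if (bp[3] > 0) log(bp[3]) else 0
  vdnn <- if (length(dnn) > 1) var(dnn) else 0
  sd1 <- sqrt(max(0, vdnn / 2))
  sd2 <- sqrt(max(0, 2 * var(nn) - vdnn / 2))
  out["SD1"] <- sd1; out["SD2"] <- sd2
  out["SD2SD1"] <- if (sd1 > 0) sd2 / sd1 else 0
  out["S"] <- pi * sd1 * sd2
  out["CSI"] <- if (sd1 > 0) sd2 / sd1 else 0
  out["CVI"] <- if (sd1 > 0 && sd2 > 0) log10(16 * sd1 * sd2) else 0
  r <- 0.2 * sd(nn)
  out["SampEn"] <- sampen_cpp(nn, 2L, r)
  out["ApEn"] <- apen_cpp(nn, 2L, r)
  # geometric features on the 1/128 s histogram
  binw <- 1000 / 128
  br <- seq(floor(min(nn) / binw) * binw, max(nn) + binw, by = binw)
  cnt <- tabulate(findInterval(nn, br), nbins = length(br) - 1)
  out["HTI"] <- n / max(cnt)
  out["TINN"] <- tinn_ms(cnt, binw)
  out
}

# TINN: baseline width of the best least-squares triangular fit to the NN
# histogram (bins of 1000/128 ms).
tinn_ms <- function(cnt, binw) {
  nb <- length(cnt)
  peak <- which.max(cnt)
  if (nb < 3 || cnt[peak] == 0) return(0)
  best <- Inf; width <- 0
  for (a in 1:peak) {
    for (b in peak:nb) {
      if (b - a < 1) next
      tri <- numeric(nb)
      up <- a:peak
      if (peak > a) tri[up] <- cnt[peak] * (up - a) / (peak - a)
      else tri[peak] <- cnt[peak]
      dn <- peak:b
      if (b > peak) tri[dn] <- cnt[peak] * (b - dn) / (b - peak)
      else tri[peak] <- cnt[peak]
      err <- sum((cnt - tri)^2)
      if (err < best) { best <- err; width <- (b - a) * binw }
    }
  }
  width
}

#' Extract the 30 HRV features per epoch
#'
#' For each epoch, features are computed on the NN intervals inside a
#' centered 5-minute (11-epoch, edge-clipped) window.  Windows with fewer
#' than `min_intervals` intervals are computed on the available data and
#' flagged; windows with fewer than 2 intervals emit zeros with a flag.
#'
#' @param nn_groups Per-epoch list of NN intervals (ms), as produced by
#'   [epoch_nn()] or [align_streams()].
#' @param grid The matching `epoch_grid`.
#' @param window_epochs Centered window length in epochs (default 11).
#' @param min_intervals Flagging threshold (default 8).
#' @param participant_id Identifier carried into the result.
#' @return A `feature_matrix` with 30 columns and a `low_data` flag
#'   attribute per epoch.
#' @export
extract_hrv_features <- function(nn_groups, grid, window_epochs = 11,
                                 min_intervals = 8,
                                 participant_id = "unknown") {
  stopifnot(length(nn_groups) == grid$n_epochs)
  n <- grid$n_epochs
  half <- floor(window_epochs / 2)
  lens <- lengths(nn_groups)
  cum <- c(0, cumsum(lens))
  all_nn <- unlist(nn_groups, use.names = FALSE)
  vals <- matrix(0, n, 30)
  flags <- logical(n)
  for (i in seq_len(n)) {
    a <- max(1, i - half); b <- min(n, i + half)
    w <- all_nn[(cum[a] + 1):cum[b + 1]]
    if (cum[b + 1] - cum[a] < 2) { flags[i] <- TRUE; next }
    if (length(w) < min_intervals) flags[i] <- TRUE
    vals[i, ] <- hrv_window_features(w)
  }
  fm <- new_feature_matrix(vals, hrv_manifest(window_epochs), grid,
                           participant_id)
  attr(fm, "low_data") <- flags
  fm
}

#' Detect breaths in a respiration waveform
#'
#' Inhalation peaks are local maxima with topographic prominence at least
#' `min_prominence` (normalized units) separated by at least
#' `min_distance_s` seconds (i.e. at most 30 breaths/min); troughs are the
#' minima between consecutive peaks; breath-to-breath (BB) intervals are
#' successive peak differences.
#'
#' @param resp A `uniform_signal`, typically in `[0, 1]`.
#' @param min_prominence Minimum peak prominence (default 0.1).
#' @param min_distance_s Minimum inter-peak distance in seconds (default 2).
#' @return A `breath_events` object: `peak_times`, `trough_times`,
#'   `bb_intervals` (seconds).
#' @export
detect_breaths <- function(resp, min_prominence = 0.1, min_distance_s = 2) {
  stopifnot(inherits(resp, "uniform_signal"))
  v <- resp$values
  empty <- structure(list(peak_times = numeric(0), trough_times = numeric(0),
                          bb_intervals = numeric(0)), class = "breath_events")
  pk <- pracma::findpeaks(v)
  if (is.null(pk) || nrow(pk) == 0) return(empty)
  ord <- order(pk[, 2])
  idx <- pk[ord, 2]; hgt <- pk[ord, 1]
  prom <- peak_prominence(v, idx, hgt)
  keep <- prom >= min_prominence
  idx <- idx[keep]; hgt <- hgt[keep]
  if (length(idx) == 0) return(empty)
  # enforce minimum spacing, keeping the higher of two merged peaks
  min_gap <- min_distance_s * resp$rate_hz
  sel <- order(-hgt)
  chosen <- integer(0)
  for (j in sel) {
    if (!length(chosen) || all(abs(idx[chosen] - idx[j]) >= min_gap))
      chosen <- c(chosen, j)
  }
  idx <- sort(idx[chosen])
  if (length(idx) == 0) return(empty)
  peak_times <- resp$t0 + (idx - 1) / resp$rate_hz
  trough_idx <- if (length(idx) > 1) {
    vapply(seq_len(length(idx) - 1), function(k) {
      win <- idx[k]:idx[k + 1]
      win[which.min(v[win])]
    }, 0L)
  } else integer(0)
  structure(list(peak_times = peak_times,
                 trough_times = resp$t0 + (trough_idx - 1) / resp$rate_hz,
                 bb_intervals = diff(peak_times)),
            class = "breath_events")
}

# topographic prominence of peaks at `idx` with heights `hgt`
peak_prominence <- function(v, idx, hgt) {
  n <- length(idx)
  prom <- numeric(n)
  for (k in seq_len(n)) {
    h <- hgt[k]
    # nearest strictly higher peak on each side (or series edge)
    left_lim <- 1
    for (j in seq_len(k - 1)) if (hgt[k - j] > h) { left_lim <- idx[k - j]; break }
    right_lim <- length(v)
    if (k < n) for (j in (k + 1):n) if (hgt[j] > h) { right_lim <- idx[j]; break }
    lo_l <- min(v[left_lim:idx[k]])
    lo_r <- min(v[idx[k]:right_lim])
    prom[k] <- h - max(lo_l, lo_r)
  }
  prom
}

rrv_window_features <- function(bb, interp_times = NULL) {
  out <- setNames(numeric(20), RRV_NAMES)
  n <- length(bb)
  if (n < 2) return(out)
  dbb <- diff(bb)
  m <- mean(bb); md <- median(bb)
  sdbb <- sd(bb)
  madbb <- median(abs(bb - md)) * 1.4826
  rmssd <- sqrt(mean(dbb^2))
  out["MeanBB"] <- m; out["MedianBB"] <- md; out["SDBB"] <- sdbb
  out["RMSSD"] <- rmssd
  out["SDSD"] <- if (length(dbb) > 1) sd(dbb) else 0
  out["CVBB"] <- if (m > 0) sdbb / m else 0
  out["CVSD"] <- if (m > 0) rmssd / m else 0
  out["MadBB"] <- madbb
  out["MCVBB"] <- if (md > 0) madbb / md else 0
  tms <- if (is.null(interp_times)) cumsum(bb) else interp_times
  bp <- band_powers(tms, bb, list(c(0, 0.04), c(0.04, 0.15), c(0.15, 0.4)),
                    interp_hz = 2)
  out["VLF"] <- bp[1]; out["LF"] <- bp[2]; out["HF"] <- bp[3]
  out["LFHF"] <- if (bp[3] > 0) bp[2] / bp[3] else 0
  out["LFn"] <- if (bp[2] + bp[3] > 0) bp[2] / (bp[2] + bp[3]) else 0
  out["HFn"] <- if (bp[2] + bp[3] > 0) bp[3] / (bp[2] + bp[3]) else 0
  vdbb <- if (length(dbb) > 1) var(dbb) else 0
  sd1 <- sqrt(max(0, vdbb / 2))
  sd2 <- sqrt(max(0, 2 * var(bb) - vdbb / 2))
  out["SD1"] <- sd1; out["SD2"] <- sd2
  out["SD2SD1"] <- if (sd1 > 0) sd2 / sd1 else 0
  r <- 0.2 * sd(bb)
  out["ApEn"] <- apen_cpp(bb, 2L, r)
  out["SampEn"] <- sampen_cpp(bb, 2L, r)
  out
}

#' Extract the 60 RRV features per epoch
#'
#' For each epoch and each window length (5, 7, 9 minutes, centered on the
#' epoch midpoint), the 20 BB-interval metrics of [rrv_manifest()] are
#' computed on the intervals whose defining (ending) inhalation peak falls
#' inside the window.  Windows with fewer than `min_breaths` breaths
#' produce an all-zero segment and set the epoch's zero-fill flag — the
#' rule used when no respiration could be recovered from a noisy signal.
#'
#' @param breaths A `breath_events` object (belt or EDR derived).
#' @param grid The matching `epoch_grid`.
#' @param window_minutes Window lengths in minutes (default 5, 7, 9).
#' @param modality "RRV" or "EDRRV" (column-name prefix).
#' @param min_breaths Zero-fill threshold (default 4).
#' @param participant_id Identifier carried into the result.
#' @return A `feature_matrix` with 60 columns and per-epoch `zero_filled`
#'   flags.
#' @export
extract_rrv_features <- function(breaths, grid, window_minutes = c(5, 7, 9),
                                 modality = "RRV", min_breaths = 4,
                                 participant_id = "unknown") {
  stopifnot(inherits(breaths, "breath_events"))
  n <- grid$n_epochs
  centers <- epoch_starts(grid) + grid$epoch_length / 2
  pk <- breaths$peak_times
  bb <- breaths$bb_intervals
  bb_end <- pk[-1]           # defining peak = ending peak of each interval
  vals <- matrix(0, n, 20 * length(window_minutes))
  filled <- matrix(FALSE, n, length(window_minutes))
  for (w in seq_along(window_minutes)) {
    hw <- window_minutes[w] * 60 / 2
    cols <- (w - 1) * 20 + 1:20
    for (i in seq_len(n)) {
      in_pk <- pk >= centers[i] - hw & pk < centers[i] + hw
      if (sum(in_pk) < min_breaths) { filled[i, w] <- TRUE; next }
      sel <- bb_end >= centers[i] - hw & bb_end < centers[i] + hw
      if (sum(sel) < 2) { filled[i, w] <- TRUE; next }
      vals[i, cols] <- rrv_window_features(bb[sel], interp_times = bb_end[sel])
    }
  }
  man <- rrv_manifest(modality, window_minutes)
  fm <- new_feature_matrix(vals, man, grid, participant_id,
                           zero_filled = apply(filled, 1, any))
  attr(fm, "zero_filled_by_window") <- filled
  fm
}

#' Assemble a modality-combination feature matrix with labels
#'
#' For classical (`target = "ml"`) models, concatenates the full ACT (370),
#' HRV (30) and RRV/ED-RRV (60) manifests as required by the combination.
#' For sequence (`target = "dl"`) models, emits the reduced inputs: raw
#' activity counts, eight basic HRV features and four simple RRV features.
#' Labels come from the recording's hypnogram collapsed to the requested
#' granularity.
#'
#' @param recording An `aligned_recording`.
#' @param combo "act", "act_hrv", "act_hrv_rrv" or "act_hrv_edrrv"
#'   (separators "+"/" " accepted).
#' @param target "ml" or "dl".
#' @param granularity Stage granularity for the labels (5, 3 or 2).
#' @return List with `features` (a `feature_matrix`) and `labels` (factor).
#' @export
assemble_features <- function(recording, combo = "act_hrv_rrv",
                              target = c("ml", "dl"), granularity = 5) {
  stopifnot(inherits(recording, "aligned_recording"))
  target <- match.arg(target)
  combo <- normalize_combo(combo)
  grid <- recording$grid
  pid <- recording$participant_id
  need_hrv <- combo != "act"
  need_rrv <- combo == "act_hrv_rrv"
  need_edr <- combo == "act_hrv_edrrv"
  if (need_rrv && is.null(recording$resp))
    stopf("combination '%s' requires a respiration signal", combo)
  if (need_edr && is.null(recording$edr))
    stopf("combination '%s' requires an EDR signal", combo)
  act <- extract_act_features(recording$activity, grid, pid)
  parts <- list(act)
  if (need_hrv)
    parts <- c(parts, list(extract_hrv_features(recording$nn_groups, grid,
                                                participant_id = pid)))
  zf <- rep(FALSE, grid$n_epochs)
  if (need_rrv || need_edr) {
    sig <- if (need_rrv) recording$resp else recording$edr
    br <- detect_breaths(sig)
    rrv <- extract_rrv_features(br, grid,
                                modality = if (need_rrv) "RRV" else "EDRRV",
                                participant_id = pid)
    zf <- rrv$zero_filled
    parts <- c(parts, list(rrv))
  }
  values <- do.call(cbind, lapply(parts, `[[`, "values"))
  manifest <- do.call(rbind, lapply(parts, `[[`, "manifest"))
  if (target == "dl") {
    full <- cbind(ACT_counts = as.numeric(recording$activity), values)
    keep <- dl_input_names(combo)
    missing <- setdiff(keep, colnames(full))
    if (length(missing)) stopf("missing DL inputs: %s",
                               paste(missing, collapse = ", "))
    values <- full[, keep, drop = FALSE]
    manifest <- data.frame(name = keep,
                           modality = c("ACT", rep("HRV", sum(grepl("^HRV_", keep))),
                                        rep(sub("_.*", "", keep[grepl("RRV_", keep)]),
                                            sum(grepl("RRV_", keep))))[seq_along(keep)],
                           statistic = sub("^[A-Z]+_", "", keep),
                           window_length_epochs = NA, window_mode = NA)
  }
  h <- recording$hypnogram
  if (granularity < h$granularity) h <- collapse_stages(h, granularity)
  labels <- factor(h$stages, levels = stage_levels(granularity))
  fm <- new_feature_matrix(values, manifest, grid, pid, zero_filled = zf)
  list(features = fm, labels = labels)
}
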