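# Epoch-grid and hypnogram data model, stage collapse, stream alignment,
# record-level QC and participant-level splitting.

STAGES_5 <- c("WAKE", "N1", "N2", "N3", "REM")
STAGES_3 <- c("WAKE", "NREM", "REM")
STAGES_2 <- c("WAKE", "SLEEP")

#' Stage labels for a given granularity
#'
#' Sleep stages are modelled at three granularities: the five AASM classes
#' (wake, N1, N2, N3, REM), a three-class scheme where N1--N3 are merged
#' into NREM, and binary sleep--wake detection.
#'
#' @param granularity 5, 3 or 2.
#' @return Character vector of valid stage labels.
#' @export
stage_levels <- function(granularity) {
  switch(as.character(granularity),
         "5" = STAGES_5, "3" = STAGES_3, "2" = STAGES_2,
         stopf("granularity must be 5, 3 or 2, got %s", granularity))
}

#' Build a 30-second epoch grid
#'
#' Epoch `i` (0-based) covers the half-open interval
#' `[start_time + epoch_length * i, start_time + epoch_length * (i + 1))`.
#' A trailing partial epoch is discarded.
#'
#' @param start_time,end_time Recording-relative times in seconds.
#' @param epoch_length Epoch length in seconds (default 30, the standard
#'   sleep-scoring unit).
#' @return An `epoch_grid` object with fields `start_time`, `epoch_length`,
#'   `n_epochs`.
#' @export
build_epoch_grid <- function(start_time, end_time, epoch_length = 30) {
  if (!is.finite(epoch_length) || epoch_length <= 0)
    stopf("epoch_length must be positive, got %s", epoch_length)
  if (!is.finite(end_time - start_time) || end_time <= start_time)
    stopf("end_time (%s) must exceed start_time (%s)", end_time, start_time)
  n <- floor((end_time - start_time) / epoch_length)
  if (n < 1) stopf("duration %s s holds no complete epoch of %s s",
                   end_time - start_time, epoch_length)
  structure(list(start_time = start_time, epoch_length = epoch_length,
                 n_epochs = as.integer(n)),
            class = "epoch_grid")
}

#' Epoch start times of a grid
#' @param grid An `epoch_grid`.
#' @return Numeric vector of epoch start times in seconds.
#' @export
epoch_starts <- function(grid) {
  grid$start_time + grid$epoch_length * (seq_len(grid$n_epochs) - 1)
}

#' Construct a hypnogram
#'
#' A hypnogram attaches one stage label per epoch of a grid, at a declared
#' granularity; labels outside the declared granularity are rejected.
#'
#' @param stages Character vector of stage labels, one per epoch.
#' @param grid An `epoch_grid` whose `n_epochs` equals `length(stages)`.
#' @param granularity 5 (default), 3 or 2.
#' @return A `hypnogram` object.
#' @export
hypnogram <- function(stages, grid, granularity = 5) {
  levels <- stage_levels(granularity)
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), levels)
  if (length(bad))
    stopf("labels not valid at granularity %d: %s", granularity,
          paste(bad, collapse = ", "))
  if (length(stages) != grid$n_epochs)
    stopf("hypnogram length %d != grid n_epochs %d",
          length(stages), grid$n_epochs)
  structure(list(stages = stages, grid = grid,
                 granularity = as.integer(granularity)),
            class = "hypnogram")
}

#' Collapse a hypnogram to a coarser stage granularity
#'
#' 5-class to 3-class maps N1, N2 and N3 to NREM; any collapse to 2 classes
#' maps all non-wake stages to SLEEP.  Wake always maps to wake and the
#' epoch grid is unchanged.
#'
#' @param h A `hypnogram`.
#' @param target_granularity 3 or 2; must be strictly coarser than
#'   `h$granularity`.
#' @return A `hypnogram` at the target granularity.
#' @export
collapse_stages <- function(h, target_granularity) {
  stopifnot(inherits(h, "hypnogram"))
  target <- as.integer(target_granularity)
  if (!target %in% c(3L, 2L) || target >= h$granularity)
    stopf("cannot collapse granularity %d to %d", h$granularity, target)
  s <- h$stages
  if (target == 3L) {
    s[s %in% c("N1", "N2", "N3")] <- "NREM"
  } else {
    s[s != "WAKE"] <- "SLEEP"
  }
  hypnogram(s, h$grid, target)
}

#' In-bed interval
#' @param start,end Seconds from the recording origin, `end > start`.
#' @return An `in_bed_interval` object.
#' @export
in_bed_interval <- function(start, end) {
  if (!is.finite(end - start) || end <= start)
    stopf("in-bed end (%s) must exceed start (%s)", end, start)
  structure(list(start = start, end = end), class = "in_bed_interval")
}

#' Uniformly sampled signal
#'
#' Plain container for a uniformly sampled waveform: values, sampling rate
#' and a time origin shared with the other datastreams of a recording.
#'
#' @param values Numeric vector of samples (finite).
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample, seconds from the recording origin.
#' @return A `uniform_signal` object.
#' @export
uniform_signal <- function(values, rate_hz, t0 = 0) {
  if (!is.finite(rate_hz) || rate_hz <= 0)
    stopf("rate_hz must be positive, got %s", rate_hz)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stopf("signal values must be finite")
  structure(list(values = values, rate_hz = rate_hz, t0 = t0),
            class = "uniform_signal")
}

signal_span <- function(x) c(x$t0, x$t0 + length(x$values) / x$rate_hz)

#' Align heterogeneous datastreams onto one epoch grid
#'
#' Restricts the epoch grid to the intersection of all stream spans and the
#' in-bed interval: epochs partially outside the intersection are dropped
#' from both features and labels.  Activity counts and stage labels are
#' resampled by epoch-start lookup; each NN interval is assigned to the
#' epoch containing its *ending* beat time (half-open epoch intervals).
#'
#' @param activity Data frame with columns `start_time_s`, `count`
#'   (30-second activity counts).
#' @param nn An `nn_series` (see [clean_rr_intervals()]) or data frame with
#'   columns `beat_time_s`, `nn_ms`.
#' @param resp Optional `uniform_signal` respiration (belt or EDR) waveform.
#' @param hypno A `hypnogram` on the recording's native grid.
#' @param in_bed An `in_bed_interval`, or NULL to use the hypnogram span.
#' @param participant_id Participant identifier string.
#' @param edr Optional `uniform_signal` EDR waveform.
#' @return An `aligned_recording`: trimmed grid, per-epoch `activity`
#'   counts, per-epoch `nn_groups` (lists of NN ms), optional `resp`/`edr`
#'   signals, and the trimmed `hypnogram`.
#' @export
align_streams <- function(activity, nn, resp = NULL, hypno, in_bed = NULL,
                          participant_id = "unknown", edr = NULL) {
  stopifnot(inherits(hypno, "hypnogram"))
  ep <- hypno$grid$epoch_length
  if (is.data.frame(nn)) nn <- list(beat_times = nn$beat_time_s,
                                    nn_ms = nn$nn_ms)
  spans <- list(
    activity = c(min(activity$start_time_s), max(activity$start_time_s) + ep),
    nn = range(nn$beat_times),
    hypnogram = c(hypno$grid$start_time,
                  hypno$grid$start_time + ep * hypno$grid$n_epochs))
  if (!is.null(resp)) spans$respiration <- signal_span(resp)
  if (!is.null(edr)) spans$edr <- signal_span(edr)
  if (!is.null(in_bed)) spans$in_bed <- c(in_bed$start, in_bed$end)
  lo <- max(vapply(spans, `[`, 0, 1))
  hi <- min(vapply(spans, `[`, 0, 2))
  # snap to the hypnogram's epoch boundaries
  lo_s <- hypno$grid$start_time + ep * ceiling((lo - hypno$grid$start_time) / ep)
  n <- floor((hi - lo_s) / ep)
  if (n < 1) {
    lim_lo <- names(spans)[which.max(vapply(spans, `[`, 0, 1))]
    lim_hi <- names(spans)[which.min(vapply(spans, `[`, 0, 2))]
    stopf("no overlapping epochs; limiting streams: %s (start), %s (end)",
          lim_lo, lim_hi)
  }
  grid <- build_epoch_grid(lo_s, lo_s + n * ep, ep)
  starts <- epoch_starts(grid)
  # epoch-start lookup into the activity stream and hypnogram
  act_idx <- match(starts, activity$start_time_s)
  if (anyNA(act_idx)) {
    # tolerate float jitter: nearest sample within half an epoch
    act_idx <- vapply(starts, function(s) {
      j <- which.min(abs(activity$start_time_s - s))
      if (abs(activity$start_time_s[j] - s) <= ep / 2) j else NA_integer_
    }, 0L)
  }
  counts <- activity$count[act_idx]
  counts[is.na(counts)] <- 0
  hyp_idx <- floor((starts - hypno$grid$start_time) / ep) + 1
  stages <- hypno$stages[hyp_idx]
  nn_groups <- group_by_epoch(nn$beat_times, nn$nn_ms, grid)
  structure(list(participant_id = participant_id, grid = grid,
                 activity = counts, nn_groups = nn_groups,
                 resp = resp, edr = edr,
                 hypnogram = hypnogram(stages, grid, hypno$granularity)),
            class = "aligned_recording")
}

# ending-beat rule over half-open epochs
group_by_epoch <- function(beat_times, nn_ms, grid) {
  idx <- floor((beat_times - grid$start_time) / grid$epoch_length) + 1
  keep <- !is.na(idx) & idx >= 1 & idx <= grid$n_epochs
  split(nn_ms[keep], factor(idx[keep], levels = seq_len(grid$n_epochs)))
}

#' Total-sleep-time quality control
#'
#' Computes total sleep time as 0.5 min per non-wake epoch and fails the
#' recording when it is below `min_tst_minutes` (default 120 min, i.e. the
#' two-hour exclusion rule).
#'
#' @param h A `hypnogram` at any granularity.
#' @param min_tst_minutes Minimum total sleep time in minutes.
#' @return List with `tst_minutes` and logical `pass`.
#' @export
qc_total_sleep_time <- function(h, min_tst_minutes = 120) {
  stopifnot(inherits(h, "hypnogram"))
  tst <- 0.5 * sum(h$stages != "WAKE") * (h$grid$epoch_length / 30)
  list(tst_minutes = tst, pass = tst >= min_tst_minutes)
}

#' Random participant-level train/test split
#'
#' Deterministic given `seed`; the train side is rounded half-up so a
#' 1120-participant cohort at fraction 0.8 yields 896 train / 224 test.
#'
#' @param ids Unique participant identifiers.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer RNG seed.
#' @return List with character vectors `train` and `test`.
#' @export
split_participants <- function(ids, train_fraction = 0.8, seed = 1) {
  if (anyDuplicated(ids)) stopf("participant ids must be unique")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must lie in (0, 1)")
  n <- length(ids)
  n_train <- floor(train_fraction * n + 0.5)
  perm <- with_seed(seed, sample(ids))
  list(train = perm[seq_len(n_train)],
       test = perm[setdiff(seq_len(n), seq_len(n_train))])
}
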