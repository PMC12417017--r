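# Recording-bundle I/O.  One directory per participant:
#   activity.csv   start_time_s, count
#   rr.csv         beat_time_s, rr_ms
#   resp.csv       header line "rate_hz,<hz>,t0,<s>", then one sample/row
#   ecg.csv        same shape as resp.csv (optional)
#   hypnogram.csv  epoch_index, start_time_s, stage
#   meta.json      participant_id, in_bed_start_s, in_bed_end_s
#   ground_truth.json  (synthetic cohorts only)

write_signal_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("rate_hz,%.10g,t0,%.10g", x$rate_hz, x$t0), con)
  writeLines(formatC(x$values, format = "g", digits = 8), con)
}

read_signal_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  rate <- as.numeric(hdr[2])
  t0 <- if (length(hdr) >= 4) as.numeric(hdr[4]) else 0
  vals <- scan(path, skip = 1, quiet = TRUE)
  uniform_signal(vals, rate, t0)
}

#' Write a recording bundle to disk
#'
#' Serializes a (simulated or imported) recording to the documented CSV /
#' JSON bundle layout, loadable again with [read_recording_bundle()].
#'
#' @param rec An `aligned_recording` or `sim_recording`.
#' @param dir Destination directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_recording_bundle <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  act <- if (!is.null(rec$raw)) rec$raw$activity
         else data.frame(start_time_s = epoch_starts(rec$grid),
                         count = rec$activity)
  write.csv(act, file.path(dir, "activity.csv"), row.names = FALSE)
  rrdf <- if (!is.null(rec$raw))
    data.frame(beat_time_s = rec$raw$rr$beat_times,
               rr_ms = rec$raw$rr$rr_ms)
  else {
    bt <- unlist(lapply(seq_along(rec$nn_groups), function(i)
      rep(epoch_starts(rec$grid)[i], length(rec$nn_groups[[i]]))))
    data.frame(beat_time_s = bt,
               rr_ms = unlist(rec$nn_groups, use.names = FALSE))
  }
  write.csv(rrdf, file.path(dir, "rr.csv"), row.names = FALSE)
  if (!is.null(rec$resp))
    write_signal_csv(rec$resp, file.path(dir, "resp.csv"))
  if (!is.null(rec$ecg))
    write_signal_csv(rec$ecg, file.path(dir, "ecg.csv"))
  h <- rec$hypnogram
  write.csv(data.frame(epoch_index = seq_len(h$grid$n_epochs) - 1,
                       start_time_s = epoch_starts(h$grid),
                       stage = h$stages),
            file.path(dir, "hypnogram.csv"), row.names = FALSE)
  span <- c(rec$grid$start_time,
            rec$grid$start_time + rec$grid$n_epochs * rec$grid$epoch_length)
  jsonlite::write_json(list(participant_id = rec$participant_id,
                            in_bed_start_s = span[1],
                            in_bed_end_s = span[2]),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  if (!is.null(rec$ground_truth))
    jsonlite::write_json(rec$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording bundle from disk
#'
#' Loads the CSV/JSON bundle written by [write_recording_bundle()] and
#' aligns the streams onto the in-bed epoch grid.
#'
#' @param dir Bundle directory.
#' @return An `aligned_recording` (with `ecg` attached when present).
#' @export
read_recording_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  act <- read.csv(file.path(dir, "activity.csv"))
  rr <- read.csv(file.path(dir, "rr.csv"))
  hdf <- read.csv(file.path(dir, "hypnogram.csv"))
  ep <- if (nrow(hdf) > 1) hdf$start_time_s[2] - hdf$start_time_s[1] else 30
  grid <- build_epoch_grid(hdf$start_time_s[1],
                           hdf$start_time_s[nrow(hdf)] + ep, ep)
  gran <- if (all(hdf$stage %in% STAGES_2)) 2
          else if (all(hdf$stage %in% STAGES_3)) 3 else 5
  h <- hypnogram(hdf$stage, grid, gran)
  resp <- if (file.exists(file.path(dir, "resp.csv")))
    read_signal_csv(file.path(dir, "resp.csv")) else NULL
  nn <- clean_rr_intervals(rr$rr_ms, rr$beat_time_s)
  rec <- align_streams(act, nn, resp = resp, hypno = h,
                       in_bed = in_bed_interval(meta$in_bed_start_s,
                                                meta$in_bed_end_s),
                       participant_id = meta$participant_id)
  if (file.exists(file.path(dir, "ecg.csv")))
    rec$ecg <- read_signal_csv(file.path(dir, "ecg.csv"))
  rec
}
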