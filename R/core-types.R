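#' Channel metadata table
#'
#' Builds the per-contact metadata carried by a recording: one row per
#' channel with its label, its role in the stimulation/recording montage,
#' its physical row on the lead, and the volts-per-count scale of the
#' acquisition chain.
#'
#' @param label character vector of unique channel labels.
#' @param role one of `"stim_anode"`, `"stim_cathode"`, `"ring_record"`,
#'   `"segment_record"`, `"unused"` (recycled).
#' @param row integer lead row index (recycled).
#' @param scale volts-per-count scale factor (recycled).
#' @return data.frame with columns `label`, `role`, `row`, `scale`.
#' @export
channel_info <- function(label, role = "ring_record", row = NA_integer_,
                         scale = 1e-6) {
  roles <- c("stim_anode", "stim_cathode", "ring_record",
             "segment_record", "unused")
  role <- match.arg(role, roles, several.ok = TRUE)
  if (anyDuplicated(label)) stopf("channel labels must be unique")
  data.frame(label = as.character(label),
             role = rep_len(role, length(label)),
             row = rep_len(as.integer(row), length(label)),
             scale = rep_len(scale, length(label)),
             stringsAsFactors = FALSE)
}

#' Stimulation event table
#'
#' Validates and normalizes a table of stimulation events. Each paired-pulse
#' trial contributes exactly two events sharing a `pair_id`: a conditioning
#' pulse and a test pulse delivered `isi_ms` milliseconds later, both with
#' the same polarity (+1/-1 encodes the anode/cathode assignment relative to
#' the reference orientation).
#'
#' @param df data.frame with columns `time_s`, `polarity`, `pair_id`,
#'   `pulse_role` ("conditioning"/"test"), `isi_ms`, `block`.
#' @param duration_s optional recording duration; events beyond it error.
#' @param sample_rate optional sampling rate used to check that the
#'   conditioning-to-test spacing matches `isi_ms` within one sample period.
#' @return the validated event data.frame, sorted by time.
#' @export
stim_events <- function(df, duration_s = NULL, sample_rate = NULL) {
  need <- c("time_s", "polarity", "pair_id", "pulse_role", "isi_ms", "block")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("events missing columns: %s", paste(miss, collapse = ", "))
  if (!all(df$polarity %in% c(-1, 1))) stopf("polarity must be +1 or -1")
  if (!all(df$pulse_role %in% c("conditioning", "test")))
    stopf("pulse_role must be 'conditioning' or 'test'")
  if (!is.null(duration_s) && any(df$time_s < 0 | df$time_s > duration_s)) {
    bad <- unique(df$pair_id[df$time_s < 0 | df$time_s > duration_s])
    stopf("events beyond recording duration for pair(s): %s",
          paste(bad, collapse = ", "))
  }
  for (pid in unique(df$pair_id)) {
    sub <- df[df$pair_id == pid, ]
    if (nrow(sub) != 2L || !setequal(sub$pulse_role, c("conditioning", "test")))
      stopf("pair %s must have exactly one conditioning and one test event", pid)
    if (sub$polarity[1] != sub$polarity[2])
      stopf("pair %s has mismatched polarities", pid)
    if (abs(sub$isi_ms[1] - sub$isi_ms[2]) > 1e-9)
      stopf("pair %s has mismatched isi_ms", pid)
    dt_ms <- 1000 * abs(sub$time_s[sub$pulse_role == "test"] -
                          sub$time_s[sub$pulse_role == "conditioning"])
    tol_ms <- if (is.null(sample_rate)) 1e-6 else 1000 / sample_rate
    if (abs(dt_ms - sub$isi_ms[1]) > tol_ms + 1e-9)
      stopf("pair %s: conditioning/test spacing %.4f ms does not match isi %.4f ms",
            pid, dt_ms, sub$isi_ms[1])
  }
  df[order(df$time_s), , drop = FALSE]
}

#' Time-series recording container
#'
#' In-memory container for a multichannel local field potential recording:
#' a channel-by-sample matrix in millivolts, channel metadata, stimulation
#' events, and free-form metadata.
#'
#' @param signals numeric matrix, channels x samples, in millivolts.
#' @param sample_rate sampling rate in Hz.
#' @param channels a [channel_info()] table (one row per signal row).
#' @param events a [stim_events()] table (may have zero rows).
#' @param meta named list of free-form metadata.
#' @return object of class `lfp_recording`.
#' @export
new_recording <- function(signals, sample_rate = 1e5, channels = NULL,
                          events = NULL, meta = list()) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1L)
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  if (is.null(channels))
    channels <- channel_info(paste0("CH", seq_len(nrow(signals))))
  if (nrow(channels) != nrow(signals))
    stopf("channels table (%d) does not match signal rows (%d)",
          nrow(channels), nrow(signals))
  rownames(signals) <- channels$label
  if (is.null(events))
    events <- data.frame(time_s = numeric(0), polarity = numeric(0),
                         pair_id = integer(0), pulse_role = character(0),
                         isi_ms = numeric(0), block = integer(0))
  duration <- ncol(signals) / sample_rate
  if (nrow(events))
    events <- stim_events(events, duration_s = duration,
                          sample_rate = sample_rate)
  structure(list(signals = signals, sample_rate = sample_rate,
                 channels = channels, events = events, meta = meta),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) x %d samples @ %g Hz (%.3f s), %d events\n",
              nrow(x$signals), ncol(x$signals), x$sample_rate,
              ncol(x$signals) / x$sample_rate, nrow(x$events)))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$signals) / rec$sample_rate

#' Long-format feature table
#'
#' A thin wrapper around data.frame enforcing key uniqueness. Units are
#' embedded in the column names (`_ms`, `_mv`, `_mvms`, dimensionless
#' otherwise) so exported CSV headers carry them.
#'
#' @param df data.frame of long-format records.
#' @param key character vector of column names forming the unique key.
#' @return data.frame with attribute `key`.
#' @export
feature_table <- function(df, key) {
  miss <- setdiff(key, names(df))
  if (length(miss)) stopf("key columns absent: %s", paste(miss, collapse = ", "))
  if (nrow(df) && anyDuplicated(df[key]))
    stopf("duplicate key rows in feature table")
  attr(df, "key") <- key
  df
}

#' Export a feature table to CSV
#'
#' Writes a stable-column-order CSV suitable for external mixed-effects
#' fitting. Errors on duplicate key rows.
#'
#' @param tbl a [feature_table()] (or plain data.frame with a `key` attribute).
#' @param path output file path.
#' @export
export_table <- function(tbl, path) {
  key <- attr(tbl, "key")
  if (!is.null(key) && nrow(tbl) && anyDuplicated(tbl[key]))
    stopf("duplicate key rows in feature table")
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [export_table()]
#' @param path CSV path.
#' @param key optional key columns to re-attach and validate.
#' @return data.frame (a feature table when `key` is given).
#' @export
read_feature_table <- function(path, key = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(key)) df else feature_table(df, key)
}
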