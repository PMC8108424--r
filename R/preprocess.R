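# Re-referencing, epoching, polarity-fold artifact removal and
# conditioning-template construction/subtraction.

#' Re-reference a recording
#'
#' `bipolar_rings` derives one channel as the difference of the two unused
#' ring contacts (local reference near the stimulation site);
#' `common_average_segments` references every directional segment to the
#' common average of all segments. Stimulation contacts are never part of a
#' montage and are dropped from the output.
#'
#' @param rec an `lfp_recording`.
#' @param montage `"bipolar_rings"` or `"common_average_segments"`.
#' @return re-referenced `lfp_recording` (events and metadata preserved).
#' @export
rereference <- function(rec, montage = c("bipolar_rings",
                                         "common_average_segments")) {
  montage <- match.arg(montage)
  ch <- rec$channels
  if (any(ch$role %in% c("stim_anode", "stim_cathode")))
    stopf("montage references a stimulation contact; drop stim channels first")
  if (montage == "bipolar_rings") {
    idx <- which(ch$role == "ring_record")
    if (length(idx) != 2L)
      stopf("bipolar_rings needs exactly 2 ring_record channels, found %d",
            length(idx))
    sig <- rec$signals[idx[1], , drop = TRUE] - rec$signals[idx[2], , drop = TRUE]
    out_ch <- channel_info(paste0(ch$label[idx[1]], "-", ch$label[idx[2]]),
                           "ring_record")
    new_recording(matrix(sig, nrow = 1L), rec$sample_rate, out_ch,
                  rec$events, rec$meta)
  } else {
    idx <- which(ch$role == "segment_record")
    if (length(idx) < 3L)
      stopf("common_average_segments needs >= 3 segment channels")
    sub <- rec$signals[idx, , drop = FALSE]
    sig <- sweep(sub, 2, colMeans(sub))
    new_recording(sig, rec$sample_rate,
                  channel_info(ch$label[idx], "segment_record"),
                  rec$events, rec$meta)
  }
}

#' Extract pulse-locked epochs for one channel
#'
#' Cuts a fixed window around every stimulation event, with t = 0 at the
#' pulse onset rounded to the nearest sample (round-half-even; at 100 kHz
#' the worst alignment error, 5 us, is below the 10 us hardware sync
#' precision).
#'
#' @param rec an `lfp_recording`.
#' @param window ms pair, default `c(-5, 16)`; must contain 0.
#' @param channel channel label or index (default: first channel).
#' @return object of class `epoch_set`: `t_ms` (shared time axis),
#'   `waveforms` (epochs x samples, mV), `meta` (per-epoch `pair_id`,
#'   `polarity`, `pulse_role`, `isi_ms`), `sample_rate`, `channel`.
#' @export
extract_epochs <- function(rec, window = c(-5, 16), channel = 1L) {
  if (window[1] > 0 || window[2] < 0) stopf("window must contain t = 0")
  if (!nrow(rec$events)) stopf("recording has no events")
  if (is.character(channel)) channel <- match(channel, rec$channels$label)
  if (is.na(channel)) stopf("unknown channel")
  fs <- rec$sample_rate
  o1 <- round(window[1] * fs / 1000); o2 <- round(window[2] * fs / 1000)
  n <- ncol(rec$signals)
  i0 <- round(rec$events$time_s * fs)            # 0-based onset sample
  bad <- which(i0 + o1 < 0 | i0 + o2 >= n)
  if (length(bad))
    stopf("events too close to recording edge for pair(s): %s",
          paste(unique(rec$events$pair_id[bad]), collapse = ", "))
  offs <- o1:o2
  wav <- t(vapply(i0, function(i) rec$signals[channel, i + offs + 1L],
                  numeric(length(offs))))
  structure(list(t_ms = offs / fs * 1000, waveforms = wav,
                 meta = rec$events[c("pair_id", "polarity", "pulse_role",
                                     "isi_ms")],
                 sample_rate = fs,
                 channel = rec$channels$label[channel]),
            class = "epoch_set")
}

#' Fold polarity-reversed epochs into de-artifacted composites
#'
#' For each (ISI, pulse role) the composite is the sum of the mean over
#' +1-polarity epochs and the mean over -1-polarity epochs. Reversing the
#' anode/cathode assignment inverts the stimulus artifact but not the
#' neural response, so the antisymmetric artifact cancels exactly and the
#' symmetric response doubles.
#'
#' @param epochs an [extract_epochs()] result.
#' @param fold `"sum"` (default, mean(+) + mean(-)) or `"mean"` (divide the
#'   sum by 2, restoring single-response amplitude).
#' @return object of class `composite_set`: `t_ms`, `waveforms`
#'   (one row per (ISI, role)), `meta` (`isi_ms`, `pulse_role`,
#'   `n_pairs_folded`), `sample_rate`.
#' @export
fold_polarity <- function(epochs, fold = c("sum", "mean")) {
  fold <- match.arg(fold)
  m <- epochs$meta
  keys <- unique(m[c("isi_ms", "pulse_role")])
  keys <- keys[order(keys$pulse_role, keys$isi_ms), , drop = FALSE]
  wav <- matrix(0, nrow = nrow(keys), ncol = ncol(epochs$waveforms))
  npairs <- integer(nrow(keys))
  for (r in seq_len(nrow(keys))) {
    sel <- m$isi_ms == keys$isi_ms[r] & m$pulse_role == keys$pulse_role[r]
    pos <- sel & m$polarity == 1; neg <- sel & m$polarity == -1
    if (sum(pos) != sum(neg) || sum(pos) == 0L)
      stopf("unbalanced polarity counts at isi %.4g ms (%d vs %d)",
            keys$isi_ms[r], sum(pos), sum(neg))
    comp <- colMeans(epochs$waveforms[pos, , drop = FALSE]) +
      colMeans(epochs$waveforms[neg, , drop = FALSE])
    if (fold == "mean") comp <- comp / 2
    wav[r, ] <- comp
    npairs[r] <- sum(sel)
  }
  structure(list(t_ms = epochs$t_ms, waveforms = wav,
                 meta = data.frame(isi_ms = keys$isi_ms,
                                   pulse_role = keys$pulse_role,
                                   n_pairs_folded = npairs),
                 sample_rate = epochs$sample_rate),
            class = "composite_set")
}

composite_rows <- function(comp, role) which(comp$meta$pulse_role == role)

#' Build the conditioning template
#'
#' Pointwise mean of all conditioning composites with ISI at or above the
#' template threshold (long ISIs, where the conditioning response is fully
#' recovered and uncontaminated). The template is used both to normalize
#' paired-pulse ratios and to subtract conditioning-response overlap from
#' test epochs.
#'
#' @param composites a [fold_polarity()] result.
#' @param min_isi ms threshold, default 20.
#' @return object of class `template_response`: `t_ms`, `waveform`,
#'   `source_isis`, `n_averaged`, `sample_rate`.
#' @export
build_template <- function(composites, min_isi = 20) {
  rows <- which(composites$meta$pulse_role == "conditioning" &
                  composites$meta$isi_ms >= min_isi)
  if (!length(rows)) stopf("no conditioning composite with isi >= %g ms", min_isi)
  structure(list(t_ms = composites$t_ms,
                 waveform = colMeans(composites$waveforms[rows, , drop = FALSE]),
                 source_isis = composites$meta$isi_ms[rows],
                 n_averaged = length(rows),
                 sample_rate = composites$sample_rate),
            class = "template_response")
}

#' Subtract the conditioning template from test composites
#'
#' For each test composite, subtracts the template time-shifted so its
#' t = 0 aligns with the conditioning pulse (at -ISI relative to the test
#' pulse), isolating activity evoked by the test stimulus alone. The shift
#' is the integer sample offset `round(isi * fs / 1000)`, matching how both
#' pulse onsets were snapped to the sample grid. Subtraction covers the
#' overlap of the shifted template support with the composite window; where
#' the template support has ended, the composite is left unchanged.
#'
#' @param composites a [fold_polarity()] result (test rows are modified,
#'   conditioning rows pass through).
#' @param template a [build_template()] result on the same time grid.
#' @return a `composite_set` with conditioning overlap removed.
#' @export
subtract_template <- function(composites, template) {
  if (length(template$t_ms) != length(composites$t_ms) ||
      max(abs(template$t_ms - composites$t_ms)) > 1e-9)
    stopf("insufficient template coverage: template grid does not match composites")
  fs <- composites$sample_rate
  out <- composites
  n <- length(template$waveform)
  for (r in composite_rows(composites, "test")) {
    k <- round(composites$meta$isi_ms[r] * fs / 1000)  # conditioning at -k samples
    # test-epoch sample j corresponds to template sample j + k
    j_max <- n - k
    if (j_max >= 1L) {
      j <- seq_len(j_max)
      out$waveforms[r, j] <- out$waveforms[r, j] - template$waveform[j + k]
    }
  }
  out
}
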