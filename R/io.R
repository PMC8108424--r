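# Minimal 16-bit EDF(+) writer/reader plus the recording-level I/O API.
#
# No EDF package exists in the supported dependency set, so the container is
# implemented directly: 256-byte ASCII header, 256 bytes per signal, then
# int16 little-endian data records. Because EDF stores whole data records,
# the true sample count is written into the 44-char reserved header field
# ("EDF+C NS=<n>") and used to trim record padding on read; third-party EDF
# readers see trailing zeros instead. Amplitudes are stored in microvolts
# (internal unit is millivolts, conversion factor 1000).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stopf("EDF header field too long: '%s'", x)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width = 8L) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d, width = -1)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  stopf("cannot format %g in %d chars", x, width)
}

write_edf <- function(signals_uv, sample_rate, labels, path,
                      phys_range = NULL) {
  nsig <- nrow(signals_uv)
  n <- ncol(signals_uv)
  # largest record duration with integral samples/record and <= 61440 bytes
  spr <- NA_integer_
  for (dur in c(1, 0.5, 0.1, 0.05, 0.02, 0.01, 0.005, 0.001)) {
    cand <- sample_rate * dur
    if (abs(cand - round(cand)) < 1e-9 && round(cand) * nsig * 2 <= 61440 &&
        round(cand) >= 1) { spr <- round(cand); rec_dur <- dur; break }
  }
  if (is.na(spr)) stopf("no valid EDF record size for sample_rate %g", sample_rate)
  nrec <- ceiling(n / spr)

  pmin_v <- pmax_v <- numeric(nsig)
  for (i in seq_len(nsig)) {
    m <- max(abs(signals_uv[i, ]), na.rm = TRUE)
    if (!is.finite(m)) stopf("non-finite samples in channel %s", labels[i])
    if (m == 0) m <- 1  # flat channel: +/-1 uV range, samples map to digital 0
    if (!is.null(phys_range)) {
      if (m > max(abs(phys_range)))
        stopf("channel %s amplitude %.6g uV exceeds declared physical range",
              labels[i], m)
      m <- max(abs(phys_range))
    }
    pmin_v[i] <- -m; pmax_v[i] <- m
  }
  # use the header's (string-rounded) physical range for digitization so the
  # round-trip is governed by the declared scale
  pmin_s <- vapply(pmin_v, edf_num, ""); pmax_s <- vapply(pmax_v, edf_num, "")
  pmin_v <- as.numeric(pmin_s); pmax_v <- as.numeric(pmax_s)

  con <- file(path, "wb"); on.exit(close(con))
  hdr_bytes <- 256L + 256L * nsig
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate 01-JAN-2000", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8), edf_pad(hdr_bytes, 8),
    edf_pad(sprintf("EDF+C NS=%d", n), 44), edf_pad(nrec, 8),
    edf_num(rec_dur, 8), edf_pad(nsig, 4))
  fld <- function(vals, w) paste(vapply(vals, edf_pad, "", width = w), collapse = "")
  hdr <- paste0(hdr,
    fld(labels, 16), fld(rep("", nsig), 80), fld(rep("uV", nsig), 8),
    paste(pmin_s, collapse = ""), paste(pmax_s, collapse = ""),
    fld(rep("-32767", nsig), 8), fld(rep("32767", nsig), 8),
    fld(rep("", nsig), 80), fld(rep(spr, nsig), 8), fld(rep("", nsig), 32))
  writeChar(hdr, con, eos = NULL)

  # symmetric digital range so physical zero maps exactly to digital zero
  scale <- (pmax_v - pmin_v) / 65534
  npad <- nrec * spr - n
  dig <- matrix(0L, nrow = nsig, ncol = nrec * spr)
  for (i in seq_len(nsig)) {
    d <- round((c(signals_uv[i, ], rep(0, npad)) - pmin_v[i]) / scale[i]) - 32767
    dig[i, ] <- as.integer(pmin(pmax(d, -32767), 32767))
  }
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    trimws(rawToChar(raw))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nsig <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(nsig), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); dims <- rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80); spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1L) stopf("heterogeneous samples-per-record unsupported")
  spr <- spr[1]
  sample_rate <- spr / rec_dur
  total <- nrec * spr
  dig <- matrix(0L, nrow = nsig, ncol = total)
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = spr * nsig, size = 2L,
                     signed = TRUE, endian = "little")
    dig[, ((r - 1L) * spr + 1L):(r * spr)] <-
      t(matrix(block, nrow = spr, ncol = nsig))
  }
  n <- total
  ns <- regmatches(reserved, regexpr("NS=[0-9]+", reserved))
  if (length(ns)) n <- min(n, as.integer(sub("NS=", "", ns)))
  sig <- matrix(0, nrow = nsig, ncol = n)
  for (i in seq_len(nsig)) {
    scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    sig[i, ] <- (dig[i, seq_len(n)] - dmin[i]) * scale + pmin[i]
  }
  list(signals_uv = sig, sample_rate = sample_rate, labels = labels,
       dims = dims)
}

#' Write a recording to EDF+ plus an event sidecar
#'
#' Waveforms go to a 16-bit EDF+ file with physical dimension microvolts
#' (internal millivolts times 1000); stimulation events go to a CSV sidecar
#' carrying every event field losslessly (columns `time_s`, `channel_set`,
#' `polarity`, `pair_id`, `pulse_role`, `isi_ms`, `block`).
#'
#' @param rec an [new_recording()] object.
#' @param path_edf output EDF path.
#' @param path_events output events CSV path.
#' @param phys_range optional declared physical range (uV); amplitudes
#'   exceeding it error before anything is written.
#' @export
write_recording <- function(rec, path_edf, path_events, phys_range = NULL) {
  stopifnot(inherits(rec, "lfp_recording"))
  write_edf(rec$signals * 1000, rec$sample_rate, rec$channels$label,
            path_edf, phys_range = phys_range)
  ev <- rec$events
  out <- data.frame(time_s = sprintf("%.9f", ev$time_s),
                    channel_set = rep(rec$meta$channel_set %||% "",
                                      nrow(ev)),
                    polarity = ev$polarity, pair_id = ev$pair_id,
                    pulse_role = ev$pulse_role,
                    isi_ms = sprintf("%.6f", ev$isi_ms), block = ev$block)
  utils::write.csv(out, path_events, row.names = FALSE, quote = FALSE)
  invisible(rec)
}

#' Read a recording from EDF+ plus an event sidecar
#'
#' Inverse of [write_recording()]: converts EDF microvolts back to internal
#' millivolts, parses and validates the event sidecar (a pair missing either
#' of its two pulses, or an event beyond the signal duration, is a structured
#' error naming the pair).
#'
#' @param path_edf EDF file path.
#' @param path_events events CSV path.
#' @return an `lfp_recording`.
#' @export
read_recording <- function(path_edf, path_events) {
  if (!file.exists(path_edf)) stopf("EDF file not found: %s", path_edf)
  if (!file.exists(path_events)) stopf("events file not found: %s", path_events)
  e <- read_edf(path_edf)
  ev <- utils::read.csv(path_events, stringsAsFactors = FALSE)
  events <- data.frame(time_s = as.numeric(ev$time_s),
                       polarity = as.numeric(ev$polarity),
                       pair_id = as.integer(ev$pair_id),
                       pulse_role = as.character(ev$pulse_role),
                       isi_ms = as.numeric(ev$isi_ms),
                       block = as.integer(ev$block))
  meta <- list()
  if ("channel_set" %in% names(ev) && nrow(ev))
    meta$channel_set <- as.character(ev$channel_set[1])
  new_recording(e$signals_uv / 1000, e$sample_rate,
                channel_info(e$labels), events, meta)
}
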