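# R1 / ERNA feature extraction, paired-pulse-ratio curves, and
# absolute/relative refractory period estimation.

check_window <- function(t_ms, window, what = "window") {
  if (length(window) != 2L || window[2] <= window[1])
    stopf("%s must be an increasing ms pair", what)
  if (window[1] < min(t_ms) - 1e-9 || window[2] > max(t_ms) + 1e-9)
    stopf("%s [%g, %g] outside waveform support [%g, %g]",
          what, window[1], window[2], min(t_ms), max(t_ms))
}

#' Estimate baseline noise SD from the pre-stimulus interval
#'
#' SD of the waveform over the baseline window (default -5 to -0.5 ms),
#' used as the reference for presence thresholds.
#'
#' @param y waveform (mV).
#' @param t_ms time axis (ms, 0 at pulse onset).
#' @param baseline ms pair.
#' @return noise SD in mV.
#' @export
estimate_noise_sd <- function(y, t_ms, baseline = c(-5, -0.5)) {
  check_window(t_ms, baseline, "baseline")
  stats::sd(y[t_ms >= baseline[1] & t_ms <= baseline[2]])
}

#' Detect the short-latency biphasic response (R1)
#'
#' The R1 peak is the largest local maximum inside `peak_window` exceeding
#' `3 * noise_sd`; the trough is the largest local minimum inside
#' `trough_window` at a latency after the peak. Samples inside the blanking
#' interval `[0, blank]` (residual artifact) are excluded. A waveform with
#' no qualifying extremum yields `present = FALSE` (not an error). The
#' rectified R1 area is integrated over `[blank, trough_window[2]]`.
#'
#' @param y waveform (mV).
#' @param t_ms time axis (ms, 0 at pulse onset).
#' @param noise_sd baseline noise SD (mV).
#' @param blank artifact blanking limit, ms.
#' @param peak_window,trough_window ms search windows.
#' @return list of class `r1_features`: `present`, `peak_lat`, `peak_amp`,
#'   `trough_lat`, `trough_amp` (positive magnitude), `area` (mV ms).
#' @export
detect_r1 <- function(y, t_ms, noise_sd = 0, blank = 0.1,
                      peak_window = c(0.1, 0.55), trough_window = c(0.4, 1.5)) {
  check_window(t_ms, peak_window, "peak_window")
  check_window(t_ms, trough_window, "trough_window")
  res <- list(present = FALSE, peak_lat = NA_real_, peak_amp = NA_real_,
              trough_lat = NA_real_, trough_amp = NA_real_,
              area = response_area(y, t_ms, c(blank, trough_window[2])))
  class(res) <- "r1_features"
  usable <- t_ms >= max(blank, peak_window[1]) & t_ms <= peak_window[2]
  pk <- local_maxima(y)
  pk <- pk[usable[pk] & y[pk] > 3 * noise_sd]
  if (!length(pk)) return(res)
  pk <- pk[which.max(y[pk])]
  res$present <- TRUE
  res$peak_lat <- t_ms[pk]; res$peak_amp <- y[pk]
  tr_ok <- t_ms >= max(trough_window[1], t_ms[pk]) & t_ms <= trough_window[2]
  tr <- local_minima(y)
  tr <- tr[tr_ok[tr] & t_ms[tr] > res$peak_lat & y[tr] < -3 * noise_sd]
  if (length(tr)) {
    tr <- tr[which.min(y[tr])]
    res$trough_lat <- t_ms[tr]; res$trough_amp <- -y[tr]
  }
  res
}

#' Detect evoked resonant neural activity (ERNA)
#'
#' ERNA is scored as the largest local maximum in the 3-7 ms post-stimulus
#' window; it is present when that peak exceeds `k_presence * noise_sd`.
#' The ERNA area is the rectified integral over the window.
#'
#' @param y waveform (mV).
#' @param t_ms time axis (ms).
#' @param noise_sd baseline noise SD (mV).
#' @param window ms pair, default `c(3, 7)`.
#' @param k_presence presence threshold multiple of `noise_sd`.
#' @return list of class `erna_features`: `present`, `peak_lat`, `peak_amp`,
#'   `area` (mV ms).
#' @export
detect_erna <- function(y, t_ms, noise_sd = 0, window = c(3, 7),
                        k_presence = 3) {
  check_window(t_ms, window, "window")
  res <- list(present = FALSE, peak_lat = NA_real_, peak_amp = NA_real_,
              area = response_area(y, t_ms, window))
  class(res) <- "erna_features"
  inw <- t_ms >= window[1] & t_ms <= window[2]
  pk <- local_maxima(y)
  pk <- pk[inw[pk]]
  if (!length(pk)) return(res)
  pk <- pk[which.max(y[pk])]
  res$peak_lat <- t_ms[pk]; res$peak_amp <- y[pk]
  res$present <- res$peak_amp > k_presence * noise_sd
  res
}

#' Rectified response area
#'
#' Trapezoidal integral of |waveform| over a time window, in mV ms.
#'
#' @param y waveform (mV).
#' @param t_ms time axis (ms).
#' @param window ms pair.
#' @export
response_area <- function(y, t_ms, window) {
  check_window(t_ms, window, "window")
  sel <- t_ms >= window[1] - 1e-9 & t_ms <= window[2] + 1e-9
  if (sum(sel) < 2L) stopf("empty window")
  trapz(t_ms[sel], abs(y[sel]))
}

#' Paired-pulse ratio curve
#'
#' For each ISI, the ratio of the test composite's rectified component area
#' (R1 window `c(blank, 1.5)` or ERNA window `c(3, 7)`) to the same area of
#' the conditioning template. Test composites should already have had the
#' conditioning template subtracted.
#'
#' @param test_composites a `composite_set` (test rows used).
#' @param template a [build_template()] result.
#' @param component `"r1"` or `"erna"`.
#' @param window override ms window for the component area.
#' @param facil_margin PPR above `1 + facil_margin` flags facilitation.
#' @return object of class `refractory_profile`: `isis` (ascending), `ppr`,
#'   `component`, `area_test`, `area_template`, `facilitation_isis`,
#'   and (until estimated) `arp = NULL`, `rrp = NULL`.
#' @export
ppr_curve <- function(test_composites, template,
                      component = c("r1", "erna"), window = NULL,
                      facil_margin = 0.05) {
  component <- match.arg(component)
  if (is.null(window))
    window <- if (component == "r1") c(0.1, 1.5) else c(3, 7)
  rows <- composite_rows(test_composites, "test")
  if (!length(rows)) stopf("no test composites")
  a_t <- response_area(template$waveform, template$t_ms, window)
  if (a_t <= 0) stopf("zero template area in component window")
  isis <- test_composites$meta$isi_ms[rows]
  ord <- order(isis)
  rows <- rows[ord]; isis <- isis[ord]
  areas <- vapply(rows, function(r)
    response_area(test_composites$waveforms[r, ], test_composites$t_ms,
                  window), numeric(1))
  ppr <- areas / a_t
  structure(list(isis = isis, ppr = ppr, component = component,
                 window = window, area_test = areas, area_template = a_t,
                 facilitation_isis = isis[ppr > 1 + facil_margin],
                 arp = NULL, rrp = NULL),
            class = "refractory_profile")
}

# Shared run-scan for the refractory rules. Returns the first ISI of the
# first run (in scan order) of `run` consecutive PPRs satisfying `cmp`.
scan_runs <- function(isis, ppr, ok, run, descending) {
  ord <- order(isis, decreasing = descending)
  ok <- ok[ord]; isis_o <- isis[ord]
  if (length(ok) < run) return(NULL)
  for (i in seq_len(length(ok) - run + 1L))
    if (all(ok[i:(i + run - 1L)]))
      return(isis_o[i:(i + run - 1L)])
  NULL
}

#' Estimate the absolute refractory period
#'
#' Scans ISIs in descending order for the first run of `run` consecutive
#' paired-pulse ratios below `threshold` and returns the largest
#' (first-encountered) ISI of that run; `NA` when no such run exists. The
#' full run endpoints are attached as attribute `"run"`.
#'
#' @param profile a [ppr_curve()] result.
#' @param threshold PPR threshold, default 0.2.
#' @param run run length, default 3.
#' @return ISI in ms, or `NA`.
#' @export
estimate_arp <- function(profile, threshold = 0.2, run = 3L) {
  if (length(profile$isis) < run) stopf("need at least %d ISIs", run)
  r <- scan_runs(profile$isis, profile$ppr, profile$ppr < threshold, run,
                 descending = TRUE)
  if (is.null(r)) return(NA_real_)
  structure(r[1], run = range(r))
}

#' Estimate the relative refractory period
#'
#' Scans ISIs in ascending order for the first run of `run` consecutive
#' paired-pulse ratios above `threshold` and returns the smallest (first)
#' ISI of that run; `NA` when no such run exists.
#'
#' @param profile a [ppr_curve()] result.
#' @param threshold PPR threshold, default 0.98.
#' @param run run length, default 3.
#' @return ISI in ms, or `NA`.
#' @export
estimate_rrp <- function(profile, threshold = 0.98, run = 3L) {
  if (length(profile$isis) < run) stopf("need at least %d ISIs", run)
  r <- scan_runs(profile$isis, profile$ppr, profile$ppr > threshold, run,
                 descending = FALSE)
  if (is.null(r)) return(NA_real_)
  structure(r[1], run = range(r))
}

#' Latency shifts of test responses relative to the conditioning template
#'
#' For each test composite, detects R1 and ERNA and reports the latency
#' change versus the template's features (positive = delayed, negative =
#' hastened). Components not detected at a given ISI are `NA`.
#'
#' @param test_composites a `composite_set` (template-subtracted test rows).
#' @param template a [build_template()] result.
#' @param noise_sd baseline noise SD; estimated from the template baseline
#'   when `NULL`.
#' @return a [feature_table()] keyed by (`isi_ms`, `component`) with columns
#'   `lat_ms`, `dlat_ms`, `amp_mv`, `area_mvms`, `present`.
#' @export
latency_shifts <- function(test_composites, template, noise_sd = NULL) {
  if (is.null(noise_sd))
    noise_sd <- estimate_noise_sd(template$waveform, template$t_ms)
  tr1 <- detect_r1(template$waveform, template$t_ms, noise_sd)
  ter <- detect_erna(template$waveform, template$t_ms, noise_sd)
  rows <- composite_rows(test_composites, "test")
  recs <- lapply(rows, function(r) {
    y <- test_composites$waveforms[r, ]; t_ms <- test_composites$t_ms
    isi <- test_composites$meta$isi_ms[r]
    r1 <- detect_r1(y, t_ms, noise_sd)
    er <- detect_erna(y, t_ms, noise_sd)
    data.frame(
      isi_ms = isi,
      component = c("r1_peak", "r1_trough", "erna"),
      lat_ms = c(r1$peak_lat, r1$trough_lat, er$peak_lat),
      dlat_ms = c(r1$peak_lat - tr1$peak_lat,
                  r1$trough_lat - tr1$trough_lat,
                  if (ter$present) er$peak_lat - ter$peak_lat else NA_real_),
      amp_mv = c(r1$peak_amp, r1$trough_amp, er$peak_amp),
      area_mvms = c(r1$area, r1$area, er$area),
      present = c(r1$present, r1$present && !is.na(r1$trough_lat),
                  er$present))
  })
  feature_table(do.call(rbind, recs), key = c("isi_ms", "component"))
}
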