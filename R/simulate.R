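# Synthetic paired-pulse session generator.
#
# Emulates the intraoperative acquisition: 100 kHz sampling, monophasic
# pulses delivered in reversed-polarity pairs over a log-spaced grid of
# interstimulus intervals (ISIs), uniform 35-45 ms inter-pair pauses, a
# stimulation-free resting prologue, and per-channel beta-band background.
# Response phenomenology: a biphasic short-latency potential (R1) with
# absolute/relative refractory dynamics and latency delay near the
# refractory period, and a later damped oscillation (ERNA) with Gaussian
# facilitation bands and latency hastening proportional to facilitation.
# Every generative parameter is echoed in the ground-truth record.

#' Simulation configuration
#'
#' Ground-truth parameters for [synthesize_session()]. Defaults follow the
#' acquisition protocol (90 ISIs of which 86 lie in 0.18-16 ms, pauses
#' uniform in 35-45 ms, 100 kHz sampling) and the reported group-mean
#' response features (R1 peak 1.10 mV at 0.31 ms, trough 0.54 mV at
#' 0.72 ms, ARP 0.56 ms, RRP 2.94 ms, ERNA 0.24 mV peaking near 4.5 ms).
#' Amplitudes are millivolts, times milliseconds unless noted.
#'
#' @param seed integer RNG seed; the whole session is a deterministic
#'   function of the configuration including this seed.
#' @param sample_rate sampling rate, Hz.
#' @param n_isi total number of unique ISIs (short grid + template ISIs).
#' @param isi_short_range ms range of the log-spaced short-ISI grid.
#' @param isi_template_range ms range of the long "template" ISIs (>= 20 ms,
#'   used downstream to build the conditioning template).
#' @param n_template_isi number of template ISIs.
#' @param reps_per_polarity repetitions of each ISI per polarity.
#' @param pause_range ms range of the uniform inter-pair pause.
#' @param rest_duration_s stimulation-free prologue used as resting data.
#' @param artifact_amp,artifact_decay stimulus artifact peak (mV) and
#'   exponential decay constant (ms); the artifact is truncated at 0.1 ms
#'   and its sign follows pulse polarity.
#' @param r1_peak_amp,r1_peak_lat,r1_trough_amp,r1_trough_lat R1
#'   difference-of-Gaussians kernel extrema (mV, ms); the kernel is
#'   calibrated so its analytic extrema land exactly on these values.
#' @param arp,rrp absolute and relative refractory periods (ms), 0 < arp < rrp.
#' @param latency_delay_max,latency_delay_tau R1 latency delay at the ARP
#'   and its exponential decay constant with ISI (ms).
#' @param erna_present logical; generate ERNA at all.
#' @param erna_amp,erna_freq,erna_onset,erna_decay ERNA damped-sinusoid
#'   amplitude (mV), carrier (Hz), onset (ms) and decay constant (ms).
#' @param facil_bands list of `c(center_ms, width_ms, gain)` Gaussian
#'   facilitation bumps multiplying the ERNA amplitude.
#' @param hasten_per_gain ms of ERNA latency hastening per unit facilitation
#'   in excess of 1.
#' @param noise_sd additive white noise SD (mV); a 1/f ("pink") component of
#'   `noise_pink_frac * noise_sd` RMS is added on top.
#' @param noise_pink_frac pink-noise RMS as a fraction of `noise_sd`.
#' @param beta_freq beta background frequency, Hz.
#' @param beta_amp_per_channel per-recording-channel beta sinusoid amplitude
#'   (mV); length 2 selects the ring montage, length >= 3 the directional
#'   segment montage.
#' @param beta_erna_coupling in a segment montage, the across-channel ERNA
#'   amplitude profile is tilted so that corr(beta amplitude, ERNA area) has
#'   the sign of this value (and R1 the opposite sign); 0 disables coupling.
#' @return object of class `sim_config` (a validated list, with the
#'   calibrated R1 kernel parameters attached as `$r1_kernel`).
#' @export
sim_config <- function(seed = 1L,
                       sample_rate = 1e5,
                       n_isi = 90L,
                       isi_short_range = c(0.18, 16),
                       isi_template_range = c(20, 30),
                       n_template_isi = 4L,
                       reps_per_polarity = 1L,
                       pause_range = c(35, 45),
                       rest_duration_s = 10,
                       artifact_amp = 15,
                       artifact_decay = 0.03,
                       r1_peak_amp = 1.10, r1_peak_lat = 0.31,
                       r1_trough_amp = 0.54, r1_trough_lat = 0.72,
                       arp = 0.56, rrp = 2.94,
                       latency_delay_max = 0.3, latency_delay_tau = 1.0,
                       erna_present = TRUE,
                       erna_amp = 0.24, erna_freq = 300,
                       erna_onset = 3.8, erna_decay = 2.0,
                       facil_bands = list(c(2.5, 0.75, 0.4),
                                          c(7.0, 1.50, 0.4)),
                       hasten_per_gain = 0.5,
                       noise_sd = 0.005,
                       noise_pink_frac = 0.5,
                       beta_freq = 20,
                       beta_amp_per_channel = c(0.005, 0.008),
                       beta_erna_coupling = 0) {
  cfg <- as.list(environment())
  if (cfg$arp <= 0 || cfg$arp >= cfg$rrp) stopf("need 0 < arp < rrp")
  if (cfg$isi_short_range[2] >= cfg$isi_template_range[1])
    stopf("isi ranges must be disjoint and ordered")
  if (cfg$n_isi <= cfg$n_template_isi)
    stopf("n_isi must exceed n_template_isi")
  amps <- c(cfg$artifact_amp, cfg$r1_peak_amp, cfg$r1_trough_amp,
            cfg$erna_amp, cfg$noise_sd, cfg$beta_amp_per_channel)
  if (any(amps < 0)) stopf("amplitudes must be >= 0")
  if (!length(cfg$beta_amp_per_channel) %in% c(2L, 3:12))
    stopf("beta_amp_per_channel must have >= 2 entries")
  cfg$r1_kernel <- calibrate_r1_kernel(cfg$r1_peak_amp, cfg$r1_peak_lat,
                                       cfg$r1_trough_amp, cfg$r1_trough_lat)
  structure(cfg, class = "sim_config")
}

# Difference-of-Gaussians R1 kernel, calibrated by fixed-point iteration so
# the analytic extrema land exactly on the configured (lat, amp) targets.
calibrate_r1_kernel <- function(peak_amp, peak_lat, trough_amp, trough_lat,
                                s1 = 0.08, s2 = 0.15) {
  p <- list(a1 = peak_amp, m1 = peak_lat, s1 = s1,
            a2 = trough_amp, m2 = trough_lat, s2 = s2)
  if (peak_amp == 0 && trough_amp == 0) return(p)
  tt <- seq(0, trough_lat + 5 * s2, by = 1e-4)
  for (it in 1:40) {
    y <- r1_kernel_eval(tt, p)
    i_pk <- which.max(y); i_tr <- which.min(y)
    p$m1 <- p$m1 + (peak_lat - tt[i_pk])
    p$m2 <- p$m2 + (trough_lat - tt[i_tr])
    if (y[i_pk] > 0) p$a1 <- p$a1 * ifelse(peak_amp > 0, peak_amp / y[i_pk], 0)
    if (y[i_tr] < 0) p$a2 <- p$a2 * ifelse(trough_amp > 0, -trough_amp / y[i_tr], 0)
    if (abs(tt[i_pk] - peak_lat) < 2e-4 && abs(tt[i_tr] - trough_lat) < 2e-4 &&
        abs(y[i_pk] - peak_amp) < 1e-9 && abs(y[i_tr] + trough_amp) < 1e-9)
      break
  }
  p
}

r1_kernel_eval <- function(t_ms, k) {
  k$a1 * exp(-(t_ms - k$m1)^2 / (2 * k$s1^2)) -
    k$a2 * exp(-(t_ms - k$m2)^2 / (2 * k$s2^2))
}

erna_kernel_eval <- function(t_ms, amp, freq_hz, onset_ms, decay_ms) {
  u <- t_ms - onset_ms
  out <- numeric(length(t_ms))
  on <- u >= 0
  out[on] <- amp * exp(-u[on] / decay_ms) * sin(2 * pi * freq_hz * u[on] / 1000)
  out
}

#' Refractory recovery gain
#'
#' Fraction of the conditioning response amplitude recovered at a given ISI:
#' 0 at or below the absolute refractory period (ARP), then
#' `1 - exp(-(isi - arp)/tau)` with `tau = (rrp - arp)/ln(50)`, so the gain
#' is exactly 0.98 at the relative refractory period (RRP) and monotone
#' nondecreasing in ISI.
#'
#' @param isi ISI in ms (vectorized).
#' @param arp,rrp absolute/relative refractory periods, ms, `0 < arp < rrp`.
#' @return gain in \[0, 1\].
#' @export
refractory_gain <- function(isi, arp, rrp) {
  if (arp >= rrp) stopf("need arp < rrp")
  tau <- (rrp - arp) / log(50)
  ifelse(isi <= arp, 0, 1 - exp(-(isi - arp) / tau))
}

#' R1 latency delay as a function of ISI
#'
#' Exponentially decaying delay of the test-pulse R1 latency,
#' `latency_delay_max * exp(-(isi - arp)/latency_delay_tau)`, emulating the
#' progressive delay observed as the ISI enters the relative refractory
#' period. Defined for `isi > arp` (below the ARP there is no response);
#' values at or below the ARP are capped at `latency_delay_max`.
#'
#' @param isi ISI in ms (vectorized).
#' @param cfg a [sim_config()].
#' @return delay in ms.
#' @export
latency_delay <- function(isi, cfg) {
  pmin(cfg$latency_delay_max,
       cfg$latency_delay_max * exp(-(pmax(isi, cfg$arp) - cfg$arp) /
                                     cfg$latency_delay_tau))
}

#' ERNA facilitation gain
#'
#' Multiplicative ERNA amplitude gain at a given ISI: Gaussian facilitation
#' bumps `1 + sum_b gain_b * exp(-(isi - center_b)^2 / (2 width_b^2))`
#' multiplied by [refractory_gain()], so facilitation (> 1) emerges inside
#' the configured bands once refractory recovery is complete.
#'
#' @param isi ISI in ms (vectorized).
#' @param cfg a [sim_config()].
#' @return gain >= 0.
#' @export
facilitation_gain <- function(isi, cfg) {
  bump <- rep(1, length(isi))
  for (b in cfg$facil_bands)
    bump <- bump + b[3] * exp(-(isi - b[1])^2 / (2 * b[2]^2))
  refractory_gain(isi, cfg$arp, cfg$rrp) * bump
}

#' Build a randomized paired-pulse schedule
#'
#' Draws the ISI grid (`n_isi - n_template_isi` log-spaced unique ISIs in
#' `isi_short_range` plus `n_template_isi` evenly spaced template ISIs in
#' `isi_template_range`), assigns each ISI `reps_per_polarity` repetitions
#' in each polarity (exact charge balance), randomizes the pair order and
#' draws uniform inter-pair pauses. Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return object of class `pp_schedule`: list with `isis` (sorted unique
#'   grid) and `pairs` (one row per pair: `isi_ms`, `polarity`, `rep`,
#'   `pause_ms`, `block`).
#' @export
build_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_short <- cfg$n_isi - cfg$n_template_isi
  short <- exp(seq(log(cfg$isi_short_range[1]), log(cfg$isi_short_range[2]),
                   length.out = n_short))
  templ <- seq(cfg$isi_template_range[1], cfg$isi_template_range[2],
               length.out = cfg$n_template_isi)
  isis <- c(short, templ)
  pairs <- expand.grid(isi_ms = isis, polarity = c(1, -1),
                       rep = seq_len(cfg$reps_per_polarity))
  with_seed(cfg$seed, {
    ord <- sample.int(nrow(pairs))
    pairs <- pairs[ord, , drop = FALSE]
    pairs$pause_ms <- stats::runif(nrow(pairs), cfg$pause_range[1],
                                   cfg$pause_range[2])
  })
  pairs$block <- ceiling(seq_len(nrow(pairs)) / (2 * cfg$n_isi))
  rownames(pairs) <- NULL
  structure(list(isis = sort(isis), pairs = pairs, cfg_seed = cfg$seed),
            class = "pp_schedule")
}

#' Synthesize a paired-pulse session with known ground truth
#'
#' Renders the full recording for a [build_schedule()] schedule: a resting
#' prologue, then for every pair a polarity-signed artifact kernel, a
#' conditioning R1 + ERNA response, and a test response scaled/delayed by
#' the generative gain functions, over per-channel beta background and
#' white + 1/f noise. Pulse onsets are snapped to the sample grid (the
#' hardware sync precision equals one sample period at 100 kHz).
#'
#' In a segment montage with `beta_erna_coupling != 0`, per-channel ERNA
#' (and, with opposite sign, R1) amplitudes are tilted along the z-scored
#' beta amplitude profile so the across-channel correlation between beta
#' power and ERNA area has the sign of the coupling.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `recording` (an `lfp_recording`) and `truth`
#'   (ground-truth record echoing every generative parameter, the per-ISI
#'   gain/delay values, the detectable refractory thresholds `arp_detect`
#'   and `rrp_detect`, and the per-channel gains).
#' @export
synthesize_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$sample_rate
  sched <- build_schedule(cfg)
  pairs <- sched$pairs
  n_pairs <- nrow(pairs)

  # pulse onsets snapped to the sample grid (hardware sync = one sample
  # period); the test offset is snapped relative to the conditioning pulse
  # so every pair at a given ISI shares the same integer sample offset
  cond_t <- test_t <- numeric(n_pairs)
  t_cur <- cfg$rest_duration_s + 0.05
  for (p in seq_len(n_pairs)) {
    cond_t[p] <- round(t_cur * fs) / fs
    test_t[p] <- cond_t[p] + round(pairs$isi_ms[p] * fs / 1000) / fs
    t_cur <- test_t[p] + pairs$pause_ms[p] / 1000
  }
  n <- ceiling((t_cur + 0.05) * fs)

  nch <- length(cfg$beta_amp_per_channel)
  segmented <- nch >= 3L
  if (segmented) {
    labels <- paste0("S", seq_len(nch)); role <- "segment_record"
    art_gain <- 1 + seq(0.3, -0.3, length.out = nch)
    resp_sign <- ifelse(seq_len(nch) <= nch / 2, 1, -1)
  } else {
    labels <- c("C2", "C3"); role <- "ring_record"
    art_gain <- c(1.4, 0.4)
    resp_sign <- c(0.75, -0.25)
  }
  erna_mag <- r1_mag <- rep(1, nch)
  if (segmented && cfg$beta_erna_coupling != 0) {
    z <- as.numeric(scale(cfg$beta_amp_per_channel))
    tilt <- 0.6 * sign(cfg$beta_erna_coupling) *
      min(1, abs(cfg$beta_erna_coupling)) * z
    erna_mag <- pmax(0.2, 1 + tilt)
    r1_mag <- pmax(0.2, 1 - tilt)
  }

  # kernels on the relative sample grid (pulse onset at sample 0)
  resp_len <- round(16e-3 * fs) + 1L
  t_rel <- (seq_len(resp_len) - 1L) / fs * 1000
  art_len <- round(0.1e-3 * fs)
  art_kernel <- cfg$artifact_amp * exp(-((seq_len(art_len) - 1L) / fs * 1000) /
                                         cfg$artifact_decay)
  r1_cond <- r1_kernel_eval(t_rel, cfg$r1_kernel)
  erna_cond <- if (cfg$erna_present)
    erna_kernel_eval(t_rel, cfg$erna_amp, cfg$erna_freq, cfg$erna_onset,
                     cfg$erna_decay) else numeric(resp_len)

  g_refr <- refractory_gain(pairs$isi_ms, cfg$arp, cfg$rrp)
  g_fac <- facilitation_gain(pairs$isi_ms, cfg)
  d_lat <- latency_delay(pairs$isi_ms, cfg)
  hasten <- cfg$hasten_per_gain * (g_fac - 1)

  signals <- matrix(0, nrow = nch, ncol = n)
  with_seed(cfg$seed + 1L, {
    tvec <- (seq_len(n) - 1L) / fs
    for (k in seq_len(nch)) {
      y <- numeric(n)
      if (cfg$noise_sd > 0) {
        y <- stats::rnorm(n, sd = cfg$noise_sd)
        if (cfg$noise_pink_frac > 0)
          y <- y + cfg$noise_sd * cfg$noise_pink_frac * pink_noise(n)
      }
      if (cfg$beta_amp_per_channel[k] > 0)
        y <- y + cfg$beta_amp_per_channel[k] *
          sin(2 * pi * cfg$beta_freq * tvec + stats::runif(1, 0, 2 * pi))
      signals[k, ] <- y
    }
  })

  add_at <- function(ch, i0, kern) {
    idx <- i0 + seq_along(kern)
    signals[ch, idx] <<- signals[ch, idx] + kern
  }
  for (p in seq_len(n_pairs)) {
    ci <- round(cond_t[p] * fs); ti <- round(test_t[p] * fs)
    if (ti + resp_len >= n) stopf("pulse train overlaps recording end")
    pol <- pairs$polarity[p]
    r1_test <- if (g_refr[p] > 0)
      g_refr[p] * r1_kernel_eval(t_rel - d_lat[p], cfg$r1_kernel)
      else numeric(resp_len)
    erna_test <- if (cfg$erna_present && g_fac[p] > 0)
      g_fac[p] * erna_kernel_eval(t_rel, cfg$erna_amp, cfg$erna_freq,
                                  cfg$erna_onset - hasten[p], cfg$erna_decay)
      else numeric(resp_len)
    for (k in seq_len(nch)) {
      add_at(k, ci, pol * art_gain[k] * art_kernel)
      add_at(k, ti, pol * art_gain[k] * art_kernel)
      add_at(k, ci, resp_sign[k] * (r1_mag[k] * r1_cond +
                                      erna_mag[k] * erna_cond))
      add_at(k, ti, resp_sign[k] * (r1_mag[k] * r1_test +
                                      erna_mag[k] * erna_test))
    }
  }

  ev <- data.frame(
    time_s = c(cond_t, test_t),
    polarity = rep(pairs$polarity, 2),
    pair_id = rep(seq_len(n_pairs), 2),
    pulse_role = rep(c("conditioning", "test"), each = n_pairs),
    isi_ms = rep(pairs$isi_ms, 2),
    block = rep(pairs$block, 2))
  rec <- new_recording(signals, fs, channel_info(labels, role),
                       ev, meta = list(channel_set = "0-1",
                                       rest_duration_s = cfg$rest_duration_s))

  tau <- (cfg$rrp - cfg$arp) / log(50)
  isis <- sched$isis
  truth <- list(
    cfg = cfg, schedule = sched,
    arp = cfg$arp, rrp = cfg$rrp,
    arp_detect = cfg$arp + tau * log(1 / (1 - 0.2)),
    rrp_detect = cfg$rrp,
    isis = isis,
    refractory_gain = refractory_gain(isis, cfg$arp, cfg$rrp),
    facilitation_gain = facilitation_gain(isis, cfg),
    latency_delay = latency_delay(isis, cfg),
    hasten = cfg$hasten_per_gain * (facilitation_gain(isis, cfg) - 1),
    channel_gains = list(artifact = art_gain, response_sign = resp_sign,
                         r1_mag = r1_mag, erna_mag = erna_mag))
  list(recording = rec, truth = truth)
}

# Unit-RMS 1/f ("pink") noise via FFT spectral shaping. Generated at a
# highly composite length (fast FFT) and truncated.
pink_noise <- function(n) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(0, seq_len(m - 1))
  f <- pmin(f, m - f)           # fold to two-sided frequency index
  w <- 1 / sqrt(pmax(f, 1))
  w[1] <- 0                     # no DC
  y <- Re(stats::fft(X * w, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}
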