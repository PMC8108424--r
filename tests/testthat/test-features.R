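r1_trace <- function(fs = 1e5, cfg = sim_config()) {
  t_ms <- seq(-5, 16, by = 1000 / fs)
  list(t_ms = t_ms, y = ppdbs:::r1_kernel_eval(t_ms, cfg$r1_kernel))
}

test_that("R1 detection finds the kernel's analytic extrema", {
  tr <- r1_trace()
  dt <- tr$t_ms[2] - tr$t_ms[1]
  f <- detect_r1(tr$y, tr$t_ms, noise_sd = 0)
  expect_true(f$present)
  expect_equal(f$peak_lat, 0.31, tolerance = dt + 1e-9)
  expect_equal(f$peak_amp, 1.10, tolerance = 1e-3)
  expect_equal(f$trough_lat, 0.72, tolerance = dt + 1e-9)
  expect_equal(f$trough_amp, 0.54, tolerance = 1e-3)
  # flat zero waveform: absent, not an error
  z <- detect_r1(numeric(length(tr$t_ms)), tr$t_ms)
  expect_false(z$present)
  # artifact confined below the blanking limit does not change detection
  y2 <- tr$y + 50 * (tr$t_ms >= 0 & tr$t_ms < 0.1)
  f2 <- detect_r1(y2, tr$t_ms, noise_sd = 0)
  expect_equal(f2$peak_lat, f$peak_lat)
  expect_equal(f2$peak_amp, f$peak_amp)
  expect_error(detect_r1(tr$y, tr$t_ms, peak_window = c(100, 101)),
               "outside waveform support")
})

test_that("ERNA detection matches the damped sinusoid's first maximum", {
  fs <- 1e5
  t_ms <- seq(-5, 16, by = 1000 / fs)
  y <- ppdbs:::erna_kernel_eval(t_ms, amp = 0.3, freq_hz = 300,
                                onset_ms = 3.0, decay_ms = 2.0)
  # analytic first maximum: onset + atan(omega * tau) / omega
  omega <- 2 * pi * 300 / 1000
  lat <- 3.0 + atan(omega * 2.0) / omega
  f <- detect_erna(y, t_ms, noise_sd = 0.01)
  expect_true(f$present)
  expect_equal(f$peak_lat, lat, tolerance = 2000 / fs)
  expect_true(f$peak_lat >= 3 && f$peak_lat <= 7)
  # raising the presence threshold above amp/noise flips presence
  f2 <- detect_erna(y, t_ms, noise_sd = 0.01, k_presence = 1000)
  expect_false(f2$present)
  z <- detect_erna(numeric(length(t_ms)), t_ms)
  expect_false(z$present)
  expect_equal(z$area, 0)
})

test_that("rectified area matches closed forms", {
  t_ms <- seq(0, 2, by = 1e-4)
  expect_equal(response_area(rep(1, length(t_ms)), t_ms, c(0.5, 1.5)), 1.0,
               tolerance = 1e-9)
  expect_equal(response_area(numeric(length(t_ms)), t_ms, c(0, 2)), 0)
  # half-sine, amplitude 1, half-period 1 ms: integral 2/pi
  y <- ifelse(t_ms <= 1, sin(pi * t_ms), 0)
  expect_equal(response_area(y, t_ms, c(0, 1)), 2 / pi, tolerance = 1e-6)
  expect_error(response_area(y, t_ms, c(1, 1)), "increasing ms pair")
})

test_that("detectors are translation-equivariant", {
  fs <- 25000
  tr <- r1_trace(fs)
  f0 <- detect_r1(tr$y, tr$t_ms, 0)
  for (k in c(-3L, 2L, 5L)) {
    yk <- if (k >= 0) c(numeric(k), tr$y[1:(length(tr$y) - k)])
          else c(tr$y[(1 - k):length(tr$y)], numeric(-k))
    fk <- detect_r1(yk, tr$t_ms, 0)
    expect_equal(fk$peak_lat - f0$peak_lat, k * 1000 / fs, tolerance = 1e-9)
    expect_equal(fk$trough_lat - f0$trough_lat, k * 1000 / fs,
                 tolerance = 1e-9)
  }
})

test_that("paired-pulse ratios are areas normalized to the template", {
  fs <- 2000
  t_ms <- seq(-5, 16, by = 1000 / fs)
  n <- length(t_ms)
  templ_wave <- exp(-(t_ms - 0.7)^2 / 0.05) - 0.5 * exp(-(t_ms - 1.1)^2 / 0.1)
  templ <- structure(list(t_ms = t_ms, waveform = templ_wave,
                          source_isis = 20, n_averaged = 1,
                          sample_rate = fs), class = "template_response")
  mk <- function(rows, isis) structure(
    list(t_ms = t_ms, waveforms = rows,
         meta = data.frame(isi_ms = isis, pulse_role = "test",
                           n_pairs_folded = 2L),
         sample_rate = fs), class = "composite_set")
  # test composites identical to the template -> ppr = 1 everywhere
  comp <- mk(rbind(templ_wave, templ_wave, templ_wave), c(1, 2, 4))
  prof <- ppr_curve(comp, templ, "r1")
  expect_equal(prof$ppr, rep(1, 3), tolerance = 1e-12)
  expect_equal(prof$isis, c(1, 2, 4))
  # all-zero tests -> ppr = 0
  prof0 <- ppr_curve(mk(matrix(0, 3, n), c(1, 2, 4)), templ, "r1")
  expect_equal(prof0$ppr, rep(0, 3))
  # zero template area errors
  templ0 <- templ; templ0$waveform <- numeric(n)
  expect_error(ppr_curve(comp, templ0, "erna"), "zero template area")
})

test_that("ARP rule: first ISI of 3 consecutive PPRs below 0.2, scanned descending", {
  prof <- list(isis = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0),
               ppr = c(0.01, 0.03, 0.05, 0.10, 0.15, 0.30, 0.60, 0.85))
  est <- estimate_arp(prof)
  expect_equal(as.numeric(est), 0.6)
  expect_equal(attr(est, "run"), c(0.4, 0.6))
  expect_true(is.na(estimate_arp(list(isis = prof$isis,
                                      ppr = rep(0.5, 8)))))
  expect_error(estimate_arp(list(isis = 1:2, ppr = c(0.1, 0.1))), "at least")
})

test_that("RRP rule: first ISI of 3 consecutive PPRs above 0.98, scanned ascending", {
  prof <- list(isis = c(2.0, 2.4, 2.8, 3.0, 3.4),
               ppr = c(0.95, 0.985, 0.99, 0.99, 1.0))
  est <- estimate_rrp(prof)
  expect_equal(as.numeric(est), 2.4)
  expect_equal(attr(est, "run"), c(2.4, 3.0))
  expect_true(is.na(estimate_rrp(list(isis = prof$isis,
                                      ppr = rep(0.9, 5)))))
})

test_that("noise-free PPR curves reproduce the generative gains pointwise", {
  cfg <- noise_free_full(seed = 13, n_isi = 30L, n_template_isi = 2L,
                         hasten_per_gain = 0)
  ses <- synthesize_session(cfg)
  comp <- fold_polarity(extract_epochs(rereference(ses$recording), c(-5, 16)))
  templ <- build_template(comp)
  test <- subtract_template(comp, templ)
  pr1 <- ppr_curve(test, templ, "r1")
  g <- refractory_gain(pr1$isis, cfg$arp, cfg$rrp)
  expect_lt(max(abs(pr1$ppr - g)), 0.02)
  per <- ppr_curve(test, templ, "erna")
  fg <- facilitation_gain(per$isis, cfg)
  expect_lt(max(abs(per$ppr - fg)), 0.02)
})

test_that("latency shifts recover the generative delay and hastening", {
  cfg <- noise_free_full(seed = 14, n_isi = 24L, n_template_isi = 2L)
  ses <- synthesize_session(cfg)
  comp <- fold_polarity(extract_epochs(rereference(ses$recording), c(-5, 16)))
  templ <- build_template(comp)
  test <- subtract_template(comp, templ)
  sh <- latency_shifts(test, templ, noise_sd = 0)
  dt <- 1000 / cfg$sample_rate
  pk <- sh[sh$component == "r1_peak" & sh$present, ]
  pred <- latency_delay(pk$isi_ms, cfg)
  expect_lt(max(abs(pk$dlat_ms - pred)), dt + 1e-9)
  # identical waveform -> zero shift (template against itself)
  comp_t <- structure(list(t_ms = templ$t_ms,
                           waveforms = matrix(templ$waveform, 1),
                           meta = data.frame(isi_ms = 10, pulse_role = "test",
                                             n_pairs_folded = 2L),
                           sample_rate = templ$sample_rate),
                      class = "composite_set")
  sh0 <- latency_shifts(comp_t, templ, noise_sd = 0)
  expect_true(all(abs(sh0$dlat_ms[sh0$present]) < 1e-12))
  # hastening: ERNA shift negative exactly where facilitation is configured
  er <- sh[sh$component == "erna" & sh$present, ]
  fg <- facilitation_gain(er$isi_ms, cfg)
  strong <- fg > 1.05
  expect_true(any(strong))
  expect_true(all(er$dlat_ms[strong] < 0))
})
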