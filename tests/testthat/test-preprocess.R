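test_that("bipolar ring derivation subtracts the second ring from the first", {
  sig <- rbind(rep(2, 100), rep(2, 100))
  rec <- new_recording(sig, 1000, channel_info(c("C2", "C3"), "ring_record"))
  out <- rereference(rec, "bipolar_rings")
  expect_equal(nrow(out$signals), 1L)
  expect_true(all(out$signals == 0))
})

test_that("common average re-referencing centers segment channels", {
  sig <- matrix(rep(1:6, each = 50), nrow = 6, byrow = FALSE)
  sig <- matrix(1:6, nrow = 6, ncol = 50)
  rec <- new_recording(sig, 1000,
                       channel_info(paste0("S", 1:6), "segment_record"))
  out <- rereference(rec, "common_average_segments")
  expect_equal(out$signals[, 1], c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
               ignore_attr = TRUE)
  # six identical constant segments -> all zero
  rec2 <- new_recording(matrix(7, nrow = 6, ncol = 50), 1000,
                        channel_info(paste0("S", 1:6), "segment_record"))
  expect_true(all(rereference(rec2, "common_average_segments")$signals == 0))
})

test_that("montages refuse stimulation contacts", {
  sig <- matrix(0, nrow = 2, ncol = 50)
  ch <- channel_info(c("A", "B"), c("stim_anode", "ring_record"))
  rec <- new_recording(sig, 1000, ch)
  expect_error(rereference(rec, "bipolar_rings"), "stimulation contact")
})

test_that("epoch extraction conserves events and aligns t = 0 to the sample", {
  cfg <- quick_cfg(seed = 3, n_isi = 10L, n_template_isi = 2L)
  rec <- rereference(synthesize_session(cfg)$recording)
  ep <- extract_epochs(rec, c(-5, 16))
  expect_equal(nrow(ep$waveforms), nrow(rec$events))  # 20 events -> 20 epochs
  expect_equal(sum(abs(ep$t_ms)) - sum(abs(ep$t_ms[ep$t_ms != 0])), 0)
  expect_true(any(ep$t_ms == 0))
  # event at an exact sample boundary aligns there
  i0 <- round(rec$events$time_s[1] * rec$sample_rate)
  w <- ep$waveforms[order(ep$meta$pair_id, ep$meta$pulse_role), ]
  expect_equal(ep$waveforms[1, ep$t_ms == 0],
               rec$signals[1, i0 + 1], ignore_attr = TRUE)
  # too-wide window errors naming offending pairs
  expect_error(extract_epochs(rec, c(-60000, 16)), "pair")
})

test_that("conditioning epochs contain the R1 peak at its analytic latency", {
  cfg <- noise_free_full(seed = 6, n_isi = 6L, n_template_isi = 2L,
                         erna_present = FALSE)
  rec <- rereference(synthesize_session(cfg)$recording)
  ep <- extract_epochs(rec, c(-5, 16))
  cond <- which(ep$meta$pulse_role == "conditioning" & ep$meta$isi_ms >= 20)[1]
  post <- ep$t_ms > 0.12           # past the artifact
  pk <- ep$t_ms[post][which.max(abs(ep$waveforms[cond, post]))]
  expect_equal(pk, 0.31, tolerance = 1000 / rec$sample_rate + 1e-9)
})

test_that("polarity folding cancels any antisymmetric artifact exactly", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 200
    a <- rnorm(n) * exp(-(1:n) / 20)   # arbitrary artifact shape
    r <- rnorm(n)                       # arbitrary response
    ep <- make_epochs(rbind(a + r, -a + r),
                      data.frame(pair_id = 1:2, polarity = c(1, -1),
                                 pulse_role = "test", isi_ms = 2))
    comp <- fold_polarity(ep)
    expect_equal(comp$waveforms[1, ], 2 * r, tolerance = 1e-12)
    expect_equal(comp$meta$n_pairs_folded, 2L)
    half <- fold_polarity(ep, fold = "mean")
    expect_equal(half$waveforms[1, ], r, tolerance = 1e-12)
  }
})

test_that("folding requires balanced polarity counts", {
  ep <- make_epochs(matrix(0, 3, 50),
                    data.frame(pair_id = 1:3, polarity = c(1, 1, -1),
                               pulse_role = "test", isi_ms = c(2, 2, 3)))
  expect_error(fold_polarity(ep), "unbalanced polarity")
})

test_that("fold and subtract are linear operators", {
  set.seed(7)
  n <- 120
  meta <- data.frame(pair_id = 1:4, polarity = c(1, -1, 1, -1),
                     pulse_role = rep(c("conditioning", "test"), each = 2),
                     isi_ms = 2)
  for (rep in 1:3) {
    w1 <- matrix(rnorm(4 * n), 4, n)
    w2 <- matrix(rnorm(4 * n), 4, n)
    f1 <- fold_polarity(make_epochs(w1, meta))
    f2 <- fold_polarity(make_epochs(w2, meta))
    f12 <- fold_polarity(make_epochs(w1 + w2, meta))
    expect_equal(f12$waveforms, f1$waveforms + f2$waveforms,
                 tolerance = 1e-12)
  }
})

test_that("template is the pointwise mean of long-ISI conditioning composites", {
  n <- 80
  meta <- data.frame(isi_ms = c(20, 22, 25, 30, 2),
                     pulse_role = c(rep("conditioning", 4), "test"),
                     n_pairs_folded = 2L)
  set.seed(1)
  wav <- matrix(rnorm(5 * n), 5, n)
  comp <- structure(list(t_ms = seq(-5, by = 1, length.out = n),
                         waveforms = wav, meta = meta, sample_rate = 1000),
                    class = "composite_set")
  templ <- build_template(comp, min_isi = 20)
  expect_equal(templ$n_averaged, 4L)
  expect_setequal(templ$source_isis, c(20, 22, 25, 30))
  expect_equal(templ$waveform, colMeans(wav[1:4, ]), tolerance = 1e-12)
  # mean of template-minus-source residuals is the zero waveform
  resid <- sweep(wav[1:4, ], 2, templ$waveform)
  expect_lt(max(abs(colMeans(resid))), 1e-12)
  # single qualifying composite -> template equals it
  t1 <- build_template(comp, min_isi = 30)
  expect_equal(t1$waveform, wav[4, ], tolerance = 1e-12)
  expect_error(build_template(comp, min_isi = 50), "no conditioning composite")
})

test_that("template subtraction recovers the test-only activity exactly", {
  fs <- 2000
  t_ms <- seq(-5, 16, by = 1000 / fs)
  n <- length(t_ms)
  set.seed(3)
  templ_wave <- rnorm(n)
  isi <- 2                       # 4 samples at 2 kHz
  k <- round(isi * fs / 1000)
  x <- rnorm(n)
  shifted <- c(templ_wave[(k + 1):n], rep(0, k))
  comp <- structure(list(
    t_ms = t_ms, waveforms = matrix(shifted + x, 1, n),
    meta = data.frame(isi_ms = isi, pulse_role = "test",
                      n_pairs_folded = 2L),
    sample_rate = fs), class = "composite_set")
  templ <- structure(list(t_ms = t_ms, waveform = templ_wave,
                          source_isis = 20, n_averaged = 1,
                          sample_rate = fs), class = "template_response")
  out <- subtract_template(comp, templ)
  expect_equal(out$waveforms[1, 1:(n - k)], x[1:(n - k)], tolerance = 1e-12)
  # where the template support has ended the composite is untouched
  expect_equal(out$waveforms[1, (n - k + 1):n],
               (shifted + x)[(n - k + 1):n], tolerance = 1e-12)
  # template support entirely before the window -> unchanged
  comp2 <- comp; comp2$meta$isi_ms <- 30
  out2 <- subtract_template(comp2, templ)
  expect_equal(out2$waveforms, comp$waveforms)
  # mismatched grids are a coverage error
  templ_bad <- templ; templ_bad$t_ms <- templ$t_ms + 0.1
  expect_error(subtract_template(comp, templ_bad), "coverage")
})

test_that("conditioning ERNA energy is removed from short-ISI test epochs", {
  # ISIs of ~2 ms below an (artificially long) ARP: the test pulse evokes
  # nothing, so all post-artifact energy in the test epoch is conditioning
  # leakage, which template subtraction must remove almost completely.
  cfg <- noise_free_full(seed = 12, n_isi = 6L, n_template_isi = 2L,
                         isi_short_range = c(2, 2.2), arp = 3, rrp = 4,
                         facil_bands = list(), hasten_per_gain = 0)
  ses <- synthesize_session(cfg)
  comp <- fold_polarity(extract_epochs(rereference(ses$recording), c(-5, 16)))
  templ <- build_template(comp)
  after <- subtract_template(comp, templ)
  r <- which(comp$meta$pulse_role == "test" & comp$meta$isi_ms < 3)[1]
  win <- comp$t_ms >= 0.12 & comp$t_ms <= 16
  e_before <- sum(comp$waveforms[r, win]^2)
  e_after <- sum(after$waveforms[r, win]^2)
  expect_gt(e_before, 0)
  expect_lt(e_after, 0.01 * e_before)
})

test_that("composite artifact-window noise respects the propagation bound", {
  cfg <- quick_cfg(seed = 31, n_isi = 8L, n_template_isi = 2L,
                   reps_per_polarity = 2L, noise_pink_frac = 0,
                   beta_amp_per_channel = c(0, 0),
                   artifact_amp = 0, r1_peak_amp = 0, r1_trough_amp = 0,
                   erna_amp = 0, erna_present = FALSE)
  ses <- synthesize_session(cfg)
  # bipolar derivation doubles the white-noise variance
  sd_ch <- cfg$noise_sd * sqrt(2)
  comp <- fold_polarity(extract_epochs(rereference(ses$recording), c(-5, 16)))
  seg <- comp$t_ms >= 0 & comp$t_ms <= 0.1
  rms <- sqrt(mean(comp$waveforms[, seg]^2))
  expect_lt(rms, 3 * sd_ch * sqrt(2) / sqrt(cfg$reps_per_polarity))
})
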