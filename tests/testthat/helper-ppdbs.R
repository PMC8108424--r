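# Shared fixtures, all generated in code.

cfg_with <- function(defaults, ...) {
  user <- list(...)
  defaults[names(user)] <- user
  do.call(sim_config, defaults)
}

# Small fast session: 25 kHz, 20 ISIs (18 short + 2 template), no rest.
quick_cfg <- function(...) {
  cfg_with(list(sample_rate = 25000, n_isi = 20L, n_template_isi = 2L,
                rest_duration_s = 0), ...)
}

# Noise-free fast variant (no white/pink noise, no beta background).
noise_free <- function(...) {
  cfg_with(list(sample_rate = 25000, n_isi = 20L, n_template_isi = 2L,
                rest_duration_s = 0, noise_sd = 0,
                beta_amp_per_channel = c(0, 0)), ...)
}

# Noise-free session at the full 100 kHz rate (default 90-ISI grid).
noise_free_full <- function(...) {
  cfg_with(list(rest_duration_s = 0, noise_sd = 0,
                beta_amp_per_channel = c(0, 0)), ...)
}

# Hand-rolled epoch_set for algebra tests.
make_epochs <- function(waveforms, meta, sample_rate = 1000,
                        t_ms = NULL) {
  if (is.null(t_ms))
    t_ms <- (seq_len(ncol(waveforms)) - 1) / sample_rate * 1000 - 5
  structure(list(t_ms = t_ms, waveforms = waveforms, meta = meta,
                 sample_rate = sample_rate, channel = "test"),
            class = "epoch_set")
}

# Independent brute-force Freeman-Halton oracle for r x 2 / r x c tables
# with small totals: explicit nested loops over first-column entries.
brute_fisher_rx2 <- function(counts) {
  R <- rowSums(counts); C <- colSums(counts); N <- sum(counts)
  lp <- function(tab) sum(lgamma(R + 1)) + sum(lgamma(C + 1)) -
    lgamma(N + 1) - sum(lgamma(tab + 1))
  lp_obs <- lp(counts)
  grid <- do.call(expand.grid, lapply(R, function(r) 0:r))
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    a <- as.numeric(grid[i, ])
    if (sum(a) != C[1]) next
    tab <- cbind(a, R - a)
    tot <- tot + if (lp(tab) <= lp_obs + 1e-12) exp(lp(tab)) else 0
  }
  min(1, tot)
}
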