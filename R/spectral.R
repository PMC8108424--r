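# Morlet-wavelet spectra, beta-band power, and beta-vs-evoked-feature
# association across directional contacts.

#' Analytic Morlet continuous wavelet transform
#'
#' FFT-filtering implementation of the analytic Morlet CWT with
#' center-frequency/bandwidth product `omega0` (default 6). Normalized so
#' that a unit-amplitude sinusoid at a row's center frequency yields
#' squared magnitude 0.5 (its variance) on that row.
#'
#' @param x real signal (mV).
#' @param sample_rate Hz.
#' @param freqs center frequencies, Hz.
#' @param omega0 Morlet parameter (cycles of the carrier per envelope SD).
#' @return complex matrix, `length(freqs)` x `length(x)`.
#' @export
morlet_cwt <- function(x, sample_rate, freqs, omega0 = 6) {
  n <- length(x)
  X <- stats::fft(x)
  nu <- (seq_len(n) - 1L) / n * sample_rate
  nu[nu > sample_rate / 2] <- nu[nu > sample_rate / 2] - sample_rate
  W <- matrix(0i, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sig_t <- omega0 / (2 * pi * f)
    H <- sqrt(2) * exp(-2 * pi^2 * sig_t^2 * (nu - f)^2) * (nu > 0)
    W[i, ] <- stats::fft(X * H, inverse = TRUE) / n
  }
  W
}

# FFT-based resampling to an integer-divisor rate (ideal low-pass).
resample_fft <- function(x, factor) {
  n <- length(x)
  m <- floor(n / factor)
  X <- stats::fft(x)
  half <- floor((m - 1) / 2)
  Y <- complex(m)
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  if (half >= 1L) Y[(m - half + 1L):m] <- X[(n - half + 1L):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Band power from the Morlet wavelet spectrum
#'
#' Renders the signal as an analytic Morlet CWT on log-spaced center
#' frequencies (default 1-200 Hz, 12 voices per octave) and integrates the
#' one-sided PSD estimate over the requested band:
#' `sum_rows 2 * sigma_t * sqrt(pi) * mean_t |W|^2 * f * dln(f)`. With this
#' normalization, band powers over a partition of the frequency axis sum to
#' the signal variance (up to wavelet leakage). Signals sampled far above
#' the analysis range are decimated first (ideal low-pass) for speed.
#'
#' @param x real signal (mV), at least 2 periods of the band's lower edge.
#' @param sample_rate Hz.
#' @param band Hz pair, default beta `c(14, 30)`.
#' @param freq_range analysis range, Hz.
#' @param voices rows per octave.
#' @param omega0 Morlet parameter.
#' @param max_analysis_rate decimate to at most this rate (Hz) before the
#'   transform when possible.
#' @return band power in mV^2.
#' @export
cwt_band_power <- function(x, sample_rate, band = c(14, 30),
                           freq_range = c(1, 200), voices = 12, omega0 = 6,
                           max_analysis_rate = 1000) {
  if (length(x) < 2 * sample_rate / band[1])
    stopf("signal too short: need >= 2 periods of %g Hz", band[1])
  fac <- floor(sample_rate / max(max_analysis_rate, 2.5 * freq_range[2]))
  if (fac >= 2) {
    x <- resample_fft(x, fac)
    sample_rate <- sample_rate / fac
  }
  freqs <- 2^(seq(log2(freq_range[1]), log2(freq_range[2]), by = 1 / voices))
  rows <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(rows)) stopf("band contains no analysis frequencies")
  W <- morlet_cwt(x, sample_rate, freqs[rows], omega0)
  mpow <- rowMeans(Mod(W)^2)
  sig_t <- omega0 / (2 * pi * freqs[rows]) # seconds when f in Hz
  dln <- log(2) / voices
  sum(2 * sig_t * sqrt(pi) * mpow * freqs[rows] * dln)
}

#' Within-subject z-score
#'
#' Centers and scales to unit SD; idempotent. Length-1 input returns 0.
#' @param x numeric vector.
#' @export
zscore <- function(x) {
  if (length(x) < 2L) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Associate resting beta power with evoked-response features
#'
#' Z-transforms each variable across a subject's channels and reports the
#' Pearson correlation (and its sign) of beta power with ERNA area and with
#' R1 area. Intended for directional montages (>= 3 channels with both
#' measures); inference is left to external mixed-effects fitting on the
#' exported table.
#'
#' @param beta per-channel resting beta power (mV^2).
#' @param erna_area per-channel ERNA rectified area (mV ms).
#' @param r1_area per-channel R1 rectified area (mV ms).
#' @param channel optional channel labels.
#' @return list with `r_erna`, `r_r1`, their signs, and the z-scored
#'   per-channel table (`table`).
#' @export
beta_feature_association <- function(beta, erna_area, r1_area,
                                     channel = NULL) {
  n <- length(beta)
  if (n < 3L || length(erna_area) != n || length(r1_area) != n)
    stopf("need >= 3 channels with beta and evoked measures")
  zb <- zscore(beta); ze <- zscore(erna_area); zr <- zscore(r1_area)
  tbl <- data.frame(channel = channel %||% paste0("ch", seq_len(n)),
                    beta_z = zb, erna_area_z = ze, r1_area_z = zr)
  list(r_erna = stats::cor(zb, ze), r_r1 = stats::cor(zb, zr),
       sign_erna = sign(stats::cor(zb, ze)),
       sign_r1 = sign(stats::cor(zb, zr)),
       n_channels = n,
       table = feature_table(tbl, key = "channel"))
}
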