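---
title: "Paired-pulse DBS evoked potentials: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-pulse DBS evoked potentials: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ppdbs)
```

## The measurement problem

Delivering pairs of DBS pulses at a controlled interstimulus interval (ISI)
and measuring how the second (test) response differs from the first
(conditioning) response probes short-term excitability of the stimulated
circuit: absolute and relative refractory periods (ARP/RRP), latency
shifts, and paired-pulse facilitation. Two obstacles stand between the raw
intraoperative LFP and those quantities.

**Stimulus artifact.** The artifact is orders of magnitude larger than the
response and overlaps its earliest part. Because swapping the anode and
cathode contacts inverts the injected field but not the evoked neural
response, averaging epochs within each polarity and *summing* the two
polarity means cancels any artifact that is antisymmetric under the swap —
whatever its shape. `fold_polarity()` implements exactly this algebra, so
the cancellation property is structural, not a fitted correction. The
composite is the sum of the two means (not their average): amplitudes are
therefore roughly twice a single response. All ratio-based quantities (PPR)
are unaffected; a `fold = "mean"` option restores single-response scale.

**Conditioning overlap.** At short ISIs the tail of the conditioning
response extends under the test response. The conditioning *template* — the
pointwise mean of conditioning composites at ISI ≥ 20 ms, where the
response is fully recovered and uncontaminated within the epoch window — is
subtracted after shifting its time origin to the conditioning pulse (at
−ISI in test-epoch time). Subtraction covers only the overlap of the
shifted template support with the epoch; once the template support has
ended, the composite passes through unchanged.

## Epochs, windows and alignment

Epochs span −5 to +16 ms around each pulse. The 5 ms pre-stimulus segment
supplies the noise baseline (`estimate_noise_sd()`, −5 to −0.5 ms); +16 ms
covers the largest analyzed test ISI, and — deliberately — equals the
template's support, so template subtraction removes conditioning activity
exactly as far out as the conditioning epoch itself was measured.
Conditioning activity beyond 16 ms is negligible (the ERNA envelope has
decayed to below 0.3% of its peak by then at the default decay constant).

Event times are stored as float seconds and rounded half-to-even to the
nearest sample at epoching. At 100 kHz the worst alignment error (5 µs) is
below the acquisition hardware's stated 10 µs sync precision, so no
sub-sample interpolation is attempted. The template shift uses the integer
offset `round(isi * fs / 1000)`, matching how the generator places the test
pulse on the sample grid relative to the conditioning pulse; an early
implementation that snapped the two pulses independently produced
pair-to-pair ±1-sample differences in the offset, which smeared the fold at
half-sample ISIs and is the reason the relative snap is load-bearing.

## Feature definitions

* **R1**: largest local maximum in 0.10–0.55 ms exceeding 3x the baseline
  noise SD, and the largest subsequent local minimum in 0.40–1.50 ms. The
  search windows are design choices centered on the reported group means
  (peak 0.31 ± 0.10 ms, trough 0.72 ± 0.11 ms); the 0.1 ms blanking bound
  excludes residual artifact. Absence of a qualifying extremum is a value
  (`present = FALSE`), not an error.
* **ERNA**: largest local maximum in 3–7 ms; present when it exceeds
  `k_presence = 3` noise SDs. The 3x rule is an invention (the source
  analysis relied on visual inspection); it is the conventional
  detection-threshold choice and is configurable.
* **Areas** are rectified trapezoidal integrals — R1 over
  [blank, 1.5] ms, ERNA over [3, 7] ms. PPR uses areas rather than peak
  amplitudes because area is robust to the latency shifts that are
  themselves an object of study; peak-based PPR remains available through
  the detector outputs.
* **ARP/RRP run rules**: the first ISI among 3 consecutive PPR < 0.2
  (ARP) / > 0.98 (RRP). The scan direction is not stated in the source
  description; scanning descending for the ARP and ascending for the RRP is
  the only reading under which the rules return interior threshold
  crossings rather than grid endpoints, and both endpoints of the
  triggering run are reported (`attr(x, "run")`, and in
  `refractory.json`).

## The synthetic world

`sim_config()` states the world once; `synthesize_session()` renders it.
Protocol parameters follow the acquisition description: 100 kHz sampling,
90 unique ISIs of which 86 are log-spaced in 0.18–16 ms and 4 lie in
20–30 ms (the template donors), every ISI delivered once per polarity
(exact charge balance), uniform 35–45 ms pauses, and a 10 s
stimulation-free prologue standing in for the resting recording. Log
spacing of the short-ISI grid is itself a choice — only the range and count
are reported — made because refractory dynamics evolve on a ratio scale.

Response phenomenology and defaults:

* **R1 kernel**: difference of two Gaussians (widths 0.08/0.15 ms),
  calibrated by fixed-point iteration so its *analytic* extrema land
  exactly on the configured (latency, amplitude) targets — defaults are the
  reported group means (1.10 mV @ 0.31 ms; −0.54 mV @ 0.72 ms). Exact
  extrema make detector tests sharp to one sample.
* **Refractory recovery**: gain 0 below the ARP, then
  `1 − exp(−(isi − arp)/τ)` with `τ = (rrp − arp)/ln 50`, so the gain is
  exactly 0.98 at the RRP — the RRP run rule's threshold. Defaults
  ARP 0.56 ms, RRP 2.94 ms (the reported means). The functional form is an
  invention; the source reports only the qualitative shape.
* **Latency delay**: `delay_max · exp(−(isi − arp)/τ_d)` (defaults 0.3 ms,
  τ_d 1 ms), emulating progressive R1 delay inside the relative refractory
  period.
* **ERNA**: damped sinusoid, 300 Hz carrier (the reported peak latency
  constrains only the onset; 250–350 Hz is the literature range for
  STN/GPi resonance), onset 3.8 ms and decay 2 ms so the first — and
  largest — oscillation maximum falls at 4.5 ms, the reported group mean.
  Facilitation multiplies the amplitude by Gaussian bumps
  (centers 2.5 and 7 ms, widths 0.75/1.5 ms, gains 0.4) times the
  refractory gain, emulating the two facilitation ranges (~1–4 and
  ~5–10 ms); latency hastens by 0.5 ms per unit facilitation above 1.
* **Background**: white noise (SD 5 µV — a realistic macroelectrode noise
  floor), a 1/f component at half that RMS, and a per-channel beta
  sinusoid (5–8 µV rings; configurable per segment). In the directional
  montage, per-channel ERNA (and oppositely R1) amplitudes are tilted
  along the z-scored beta profile so the across-channel beta–ERNA
  correlation has the sign of `beta_erna_coupling`.
* **Montage**: two ring contacts (artifact gains 1.4/0.4, response gains
  0.75/−0.25, so the bipolar derivation carries unit gain for both) or six
  directional segments with a sign flip between rows — the phase reversal
  seen on directional leads — which also keeps the common average nearly
  response-free.

What a green test does **not** establish: the generator has no biophysics
(no conductance-based circuit, no electrode field model), its noise is
stationary and Gaussian, the artifact is perfectly antisymmetric (real
asymmetries from electrode polarization survive folding), and single-trial
variability per (ISI, polarity) is absent at the default one repetition.
Green acceptance means the *pipeline* recovers the stated world's
parameters, not that the world is right.

## Parameter recovery and the detectable ARP

The ARP estimator returns the ISI at which the PPR curve crosses 0.2. For
the generator's recovery law that crossing sits at
`arp + τ·ln(1.25)` — about 0.14 ms above the configured `arp`, a
deterministic offset, not an estimation error. Ground truth for recovery
tests is therefore the curve's 0.2-crossing, emitted as `arp_detect` in the
ground-truth record; the RRP needs no such distinction because the gain
equals 0.98 exactly at `rrp` (`rrp_detect = rrp`). Recovery is asserted as
a median over 20 seeded sessions within one local grid step; the RRP
median sits right at that boundary at the default SNR, because near the
RRP the gain curve is nearly flat (slope ≈ 0.03/ms) and the 0.98-threshold
crossing is intrinsically noise-sensitive — the same reason the reported
between-trajectory RRP spread (±1.05 ms) is an order of magnitude wider
than the ARP spread (±0.08 ms).

## Spectral choices

The Morlet parameter (center-frequency x bandwidth product) is 6 — the
transform family was named without parameters. Analysis frequencies are
log-spaced, 12 per octave over 1–200 Hz; signals sampled far above the
range are decimated by an ideal FFT low-pass first. Band power is computed
as a one-sided PSD integral over the band rows, normalized so a unit
sinusoid at a row center contributes its variance (0.5). A stated
"time–frequency mean over band rows" cannot satisfy a Parseval-style
partition check (sums of means have no variance interpretation), so the
integral form is used; it passes the same selectivity and mixture
invariances and additionally recovers broadband variance over a partition
to within the stated 20% wavelet-leakage tolerance.

## Exact statistics

The Freeman–Halton test enumerates all margin-fixed tables (probability
ordering, tie tolerance 1e-12), which is exact and fast at the totals that
occur here (≤ 21); a seeded Monte Carlo fallback via `r2dtable` covers
larger tables. On the packaged ERNA-presence counts (5/8, 4/5, 0/6) the
enumeration gives p = 0.01702, agreeing with `stats::fisher.test` to eight
decimals; the summary value printed in the source (0.018) is not
reproducible under probability ordering, chi-square ordering, or mid-p
variants, and the enumerated value is treated as correct. The two-tailed
binomial is the doubled smaller tail capped at 1 — the definition that
reproduces the printed 0.031 for 6/6 concordance (the alternative 0.039
printed once elsewhere in the source corresponds to no standard
definition; 0.031 is used). Confidence intervals use t quantiles
(df = n − 1), which reproduce the printed intervals to ~0.1.

## I/O and determinism

Recordings travel as 16-bit EDF+ (physical unit µV; internal unit mV,
conversion x1000) plus a CSV event sidecar, because EDF annotations cannot
carry structured pair metadata losslessly. No EDF implementation exists in
the supported dependency set, so a minimal writer/reader is built in; the
true sample count is stored in the reserved header field (`NS=<n>`) so
round-trips are exact despite record padding, and the digital range is the
symmetric −32767..32767 so physical zero is representable exactly. Every
random choice flows from the configuration seed through isolated RNG
scopes, so identical configurations give bit-identical recordings and
byte-identical report bundles; the run manifest deliberately excludes
timestamps.

## Known limitations

Blocks are an opaque label (how ISIs map to acquisition blocks is not
specified); mixed-effects inference on latency/area trends is out of scope
by design — the long-format tables are exported for external fitting; the
beta–evoked association is reported per subject only; and the EDF reader
supports only the homogeneous-rate files this package writes.
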