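Package: ppdbs
Title: Paired-Pulse Deep Brain Stimulation Evoked Potential Analysis
Version: 0.1.0
Authors@R: person("ppdbs", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for subcortical local field potentials evoked
    by paired deep-brain-stimulation pulses. Implements stimulus-artifact
    cancellation by anode/cathode polarity reversal, conditioning-template
    construction and subtraction, detection of the short-latency biphasic
    response (R1) and of evoked resonant neural activity (ERNA), paired-pulse
    ratio curves with absolute/relative refractory period estimation,
    Morlet-wavelet beta-band power, and exact small-sample statistics
    (Freeman-Halton Fisher test, two-tailed binomial). A synthetic session
    generator with known ground truth stands in for intraoperative recordings
    and makes every stage testable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
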