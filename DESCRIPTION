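Package: drgephys
Title: Excitability and Action-Potential Analysis for Sensory-Neuron Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for whole-cell patch-clamp studies of intrinsic
    plasticity in small-diameter dorsal root ganglion (DRG) neurons. Provides
    action-potential detection and waveform metrology (threshold, amplitude,
    overshoot, rise, fall, half-width, shoulder), rheobase and suprathreshold
    excitability measures from ramp and step current-injection families,
    rule-based firing-pattern classification (single, delayed, repeated),
    voltage-clamp current isolation (leak subtraction, sodium-current IV
    curves, A-type potassium current by prepulse subtraction), optogenetic
    firing-fidelity analysis, and cohort-level statistics including exact
    tests and RNA-seq TPM filtering rules. A conductance-based single
    compartment neuron simulator generates cohorts of recordings with known
    ground truth, emulating control, sustained-depolarization (30 mM KCl),
    recovery, and optogenetic-stimulation conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
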