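Package: stvep
Title: Single-Trial Visual Evoked Potential Analysis
Version: 0.1.0
Authors@R:
    person("Headache", "Electrophysiology", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of pattern-reversal visual evoked
    potentials (VEPs) recorded from a single occipital channel. Implements
    the single-trial VEP amplitude statistic (the signed mean voltage of
    each post-stimulus epoch, grand-averaged over un-artifacted trials),
    the conventional averaged-waveform N1-P1 peak-to-peak analysis, the
    preprocessing chain that links them (DC subtraction, zero-phase 1-100 Hz
    band-pass, stimulus-locked epoching, 2-SD epoch-mean artifact
    rejection), and two-group statistics (Shapiro-Wilk screening, pooled
    Student t-tests on raw values or printed summaries). A synthetic-data
    module generates continuous recordings with a phase-locked biphasic
    N1-P1 complex, a latency-jittered induced deflection, background noise
    and artifact epochs, calibrated so designed single-trial amplitudes are
    recovered through the full measurement chain, plus a seven-trial
    demonstration of how waveform averaging destroys unsynchronized
    stimulus-induced activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
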