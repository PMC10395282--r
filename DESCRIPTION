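Package: driveload
Title: Eye-Event-Locked EEG Analysis of Continuous Driver Task Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous estimation of driver mental load from the
    EEG and for eye-event-locked analysis of cognitive processing during
    simulated driving. A route is cut into 10-m track segments whose task
    load (low/medium/high) is classified from the difference of z-scored
    posterior alpha and frontal theta wavelet power. Blinks, saccades and
    fixations are detected from ocular independent components (Gaussian
    blink fits, saccade template correlation); blink- and fixation-locked
    ERPs, lateralized components (phasic/tonic ERL, CNV) and saccade-locked
    spectral perturbations are measured per load level and saccade type and
    tested with repeated-measures ANOVA (Greenhouse-Geisser correction,
    adjusted partial eta squared, jackknife peak scoring) and cluster-based
    permutation statistics. A synthetic driving-EEG generator with known
    ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
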