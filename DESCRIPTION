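Package: earmech
Title: Auditory Biomechanics and Ear Transcriptomics of Mosquito Flagellar
    Receivers
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for laser-Doppler-vibrometry recordings of insect
    antennal (flagellar) sound receivers and for intersectional classification
    of differential-expression results from ear (pedicel) RNA-seq. Fits a
    forced damped harmonic oscillator to free-fluctuation velocity spectra,
    estimates apparent antennal mass by equipartition and active-hearing power
    gain from active/passive fluctuation energies, fits a two-state
    gating-spring transducer model to force-step data, extracts mechanical and
    electrical best frequencies from linear frequency sweeps with
    sigmoid-based displacement-gain estimation, classifies transcripts into
    intersectional male-upregulation subsets from three pairwise
    differential-expression tables, and applies a normality-gated statistical
    decision tree to grouped measurements. Includes seeded simulators
    (Langevin oscillator traces, sweep trials, gating experiments,
    differential-expression tables with planted subset structure) so every
    stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
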