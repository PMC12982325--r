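Package: ssvepDepth
Title: SSVEP Stimulus Design, Simulation and Decoding Across Virtual Depths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying steady-state visual evoked potentials (SSVEP)
    elicited by frame-locked flicker stimuli presented at several virtual
    depths in mixed-reality and virtual-reality head-mounted displays.
    Provides refresh-locked stimulus design (visual-angle geometry,
    square-wave flicker, blocked trial schedules), a calibrated synthetic
    multi-channel EEG generator with 1/f background, alpha activity and
    occipitally weighted evoked components, a preprocessing chain
    (zero-phase Butterworth band-pass, epoching, decimation, amplitude-based
    rejection), three decoders (canonical correlation analysis, filter-bank
    CCA with weighted subband fusion, and task-related component analysis
    spatial filtering), and evaluation utilities (narrow-band spectral
    signal-to-noise ratio in dB, stratified Monte-Carlo validation splits,
    classification accuracy, Wilcoxon signed-rank tests with Bonferroni
    correction, and linear feature-versus-SNR fits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), signal, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'decode-cca.R'
    'decode-trca.R'
    'evaluate.R'
    'generator.R'
    'io.R'
    'pipeline.R'
    'preprocess.R'
    'stimulus.R'
    'utils.R'
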