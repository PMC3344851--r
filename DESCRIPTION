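Package: rsnica
Title: Automated Selection and Group Analysis of Resting-State Networks
    from Spatial ICA of BOLD fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes 4D resting-state BOLD runs into spatial independent
    components and selects the component carrying a target functional network
    (e.g. the auditory resting-state network) fully automatically, using an
    anticorrelation-corrected score that combines ROI connectivity-graph edge
    counts, an anticorrelation weight against designated opposing regions, and
    a fingerprint-based neuronal-likeness weight.  Includes temporal
    detrending/high-pass filtering and Gaussian spatial smoothing, per-subject
    residualized component beta maps, random-effects group T maps with
    false-discovery-rate control, Monte-Carlo cluster-extent thresholding, and
    a ground-truth phantom generator so the whole chain is testable without
    acquired data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
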