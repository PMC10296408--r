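Package: fnirsVHDR
Title: Simulation and Analysis of Visually Evoked Hemodynamic Responses in
    Multichannel fNIRS
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for event-related functional near-infrared
    spectroscopy (fNIRS) of the occipital cortex: a forward simulator that
    generates dual-wavelength recordings with stimulus-locked hemodynamic
    responses, physiological noise and motion artifacts; modified
    Beer-Lambert conversion between optical density and hemoglobin
    concentration changes; motion-artifact detection and correction and
    zero-phase band-pass filtering; block averaging with peak
    amplitude/latency extraction, best-channel and channel-average
    readouts, hemisphere peaks and a laterality index; and the group-level
    statistical plan (paired and independent t tests, split-plot mixed
    ANOVA, Spearman correlations with clinical scores, Benjamini-Hochberg
    false discovery rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, TimeCourse, Preprocessing, StatisticalMethod
RoxygenNote: 7.3.3
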