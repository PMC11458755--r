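Package: gevitrain
Title: Analysis and Simulation of Evoked Depolarizations in Wide-Field
    Voltage Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying synaptically evoked cortical
    depolarizations recorded with genetically encoded voltage indicators
    (GEVI) in wide-field movies. Converts raw fluorescence stacks into
    ROI traces (dF/F with polarity inversion, exponential photobleach
    correction, sweep and spatial averaging, Gaussian low-pass and RC
    high-pass filtering), extracts stimulus-locked per-pulse peaks from
    10-pulse stimulation trains at 20/40/83 Hz, and computes temporal
    summation efficacy (Peak-2/Peak-1 ratio, maximal train
    depolarization) and spatial propagation efficacy (inter-ROI
    amplitude ratios) with group-level statistics (mean +/- SEM, one-way
    ANOVA, Tukey HSD, significance stars). A forward-model simulator
    generates movies with known ground truth so every pipeline stage is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tiff,
    tools,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
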