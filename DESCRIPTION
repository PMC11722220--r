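Package: dlamr
Title: Laminar Electrophysiology and Calcium Imaging Analysis for
    Dichoptic Stimulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of laminar recordings from mouse binocular
    visual cortex under dichoptic (two-eye, conflicting) grating stimulation:
    local field potential conditioning, visually evoked potential (VEP)
    component measurement, current-source-density (CSD) based laminar
    alignment, multiunit activity envelope (MUAe) with interblock z-scoring,
    regular-/fast-spiking unit classification with windowed firing statistics,
    neuropil-corrected calcium dF/F, and repeated-measures inference with
    Greenhouse-Geisser correction and Sidak contrasts. Includes a synthetic
    laminar-session generator with known ground truth for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
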