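Package: cestpH
Title: AACID CEST-MRI Simulation and Intracellular pH Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for ratiometric intracellular pH
    imaging with chemical exchange saturation transfer (CEST) MRI. Provides a
    multi-pool Bloch-McConnell simulator with pH-dependent amide and amine
    exchange, digital phantoms with scripted tissue pH, B0 inhomogeneity and
    Rician noise, Z-spectrum processing (reference normalization, repeat
    averaging, smoothing-spline interpolation at 1-Hz resolution, WASSR-based
    per-voxel B0 correction), amine/amide concentration-independent detection
    (AACID) and calibrated pH parametric maps, ROI time-course summaries, and
    the accompanying statistical battery (Shapiro-Wilk, two-way repeated
    measures ANOVA with Greenhouse-Geisser correction, Tukey post-hoc tests,
    paired t-tests).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    car,
    withr,
    optparse
Config/testthat/edition: 3
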