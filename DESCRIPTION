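Package: tuberfield
Title: Electric-Field Modelling and Stained-Slice Image Analysis for
    Potato-Model Electroporation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing irreversible-electroporation
    (IRE) experiments in the potato tuber model. Solves the steady-state
    electric potential between a pair of parallel needle electrodes with a
    sparse finite-difference Laplace solver, derives iso-field contours and
    predicted IRE/reversible-electroporation ablation zones, generates
    seeded synthetic photographs of TTC-stained and melanin-accumulated
    tuber slices with exact ground-truth masks (including staining-time
    kinetics and the star-shaped inner-medulla artifact), segments such
    images by colour thresholding with ruler-based scale calibration, and
    emulates the electrical observables (saturating per-pulse current
    trains, 10-Hz conductivity change ratios). A statistics layer and a
    reproducible end-to-end pipeline relate ablation areas to the
    electrical measurements via Pearson correlation and paired t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    png,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    yaml
Config/testthat/edition: 3
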