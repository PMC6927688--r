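Package: afmgating
Title: Single-Molecule Gating Analysis of High-Speed AFM Movies of Pentameric Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize ligand-dependent gating of membrane channels in
    high-speed atomic force microscopy (HS-AFM) time-lapse topographs, developed around
    the Mg2+-gated pentameric channel CorA. Includes a ground-truthed movie simulator
    (tip-convolved raster-scan image formation over a Markov gating model), image
    preprocessing (plane flattening, drift correction, particle detection and tracking,
    rotational averaging, morphometrics), DeltaHeight trace and kymograph extraction,
    step-transition state idealization with minimum-description-length model selection,
    dwell-time and transition statistics, four-class conformational classification with
    occupancy and transition-map summaries, equilibrium titration (Kd) fitting, and
    elastic-rod estimates of transmembrane-helix bending.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
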