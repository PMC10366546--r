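Package: AFMCrystal
Title: Assembly Dynamics of 2D Protein Crystals from High-Speed AFM Height Movies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies two-dimensional protein-crystal assembly on supported
    lipid bilayers from high-speed atomic force microscopy (HS-AFM) height
    movies. Provides lattice-geometry extraction by autocorrelation and FFT
    peak analysis, height-profile and protrusion statistics with notched-box
    summaries, automated stripe tracing with association/dissociation
    kinetics and cumulative surface coverage, frame-averaged stability maps,
    and structure-based pseudo-AFM rendering from PDB coordinates via
    tip-shape grayscale dilation. A ground-truthed synthetic HS-AFM movie
    generator emulating dimer-wise crystal growth of a membrane-bound
    aegerolysin makes every analysis stage testable without raw instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    tiff,
    jsonlite,
    bio3d,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
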