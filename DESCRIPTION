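Package: embryotfm
Title: Traction Force Microscopy and Biomechanics of Embryo Implantation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for embryo-substrate biomechanics on soft
    elastic hydrogels: rigid drift registration of fluorescent-bead image
    stacks, PIV-style displacement fields against a relaxed reference,
    regularized Fourier-transform traction cytometry (FTTC) on a
    linear-elastic half-space, per-frame force metrics (max/mean traction,
    contact area, total force), force-dynamics statistics (peak detection,
    inter-peak periodicity, peak-displacement association, pre/post
    treatment comparison, F-actin/traction correlation), morphometrics
    (circularity, lineage-interface geometry, migration statistics, MSD,
    adhesion-onset breakpoints), Hertzian spherical-indentation fitting
    with curve quality control, and nuclear-to-cytoplasmic YAP ratio
    quantification. A forward simulator generates every input with known
    ground truth so each stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
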