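Package: dualscreen
Title: Tiered Analysis of Dual-Luciferase siRNA Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tiered (primary/secondary/tertiary)
    genome-scale siRNA screens read out with a dual-luciferase reporter
    (firefly under an inducible promoter, renilla under a constitutive
    promoter). Provides readers and writers for per-well deposit-schema
    tables, 384-well plate quality control (fold induction, transfection
    efficiency by renilla knockdown, positive-control reduction, saturation,
    plate-uniformity edge-effect testing, replicate CV and correlation),
    per-plate median normalization and robust z-scoring, tier-specific
    aggregation to gene scores (replicate mean, six-siRNA gene median),
    threshold-based hit calling with expression filtering and activity-score
    binning, multi-ligand tertiary confirmation, and a calibrated synthetic
    screen generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
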