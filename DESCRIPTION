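Package: rnfbtrace
Title: Automatic Retinal Nerve Fiber Bundle Tracing from En-Face
    Orientation Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates en-face retinal nerve fiber layer (RNFL) orientation
    fields from three sources -- a parametric average-trajectory model of
    nerve fiber bundle paths, depth-averaged Stokes-vector optic-axis maps
    from polarization-sensitive OCT, and fingerprint-style ridge orientation
    analysis of RNFL intensity projections -- calibrates and fuses them into
    a single orientation map, integrates nerve fiber bundle trajectories by
    streamline tracing toward the optic nerve head, and quantifies trace
    agreement with circular statistics (entry-angle range and offset,
    intraclass correlation, polar-resampled trace RMSE) grouped by
    Garway-Heath optic nerve head sectors.  A synthetic phantom generator
    renders ridge-textured projections, polarization volumes and layer
    boundaries from a known ground-truth field so that the whole pipeline
    can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
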