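Package: driftback
Title: Backtracked Lagrangian Dispersal and Molecular Surveillance for
    Tracing Marine Introductions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the likely source regions of a cryptogenic
    marine organism that dispersed on surface currents. Provides a
    surface-restricted Lagrangian particle integrator (fourth-order
    Runge-Kutta advection plus a horizontal random-walk diffusion term) that
    runs forward or backward in time over gridded velocity fields, a one
    degree hexagonal settlement grid activated by coastal habitat polygons,
    drifter-based calibration of horizontal diffusivity by minimum passing
    distance, landing tallies with region aggregation and rank-sum
    covariate tests, a pooled-qPCR environmental DNA screening decision
    pipeline, and percent-identity ranking of DNA barcodes against a
    reference organism. A synthetic-data module generates analytic velocity
    fields, island coastlines, drifter tracks, ENSO phase series,
    amplification curves and sequence families with known ground truth so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ncdf4,
    stats,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
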