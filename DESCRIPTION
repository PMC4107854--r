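Package: dendroca
Title: Diameter-Dependent Calcium Dynamics in Dendritic Compartmental Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modeling intracellular calcium dynamics in dendritic
    compartments and for quantifying how dendrite diameter shapes calcium
    transients. Implements phenomenological single-pool models under the
    legacy constant surface-to-volume-ratio volume convention and the
    corrected annular-shell convention, buffered calcium reaction-diffusion
    over concentric radial shells under variable-depth, fixed-depth and
    hybrid discretization schemes, a deterministic axisymmetric (r,z)
    finite-volume reference solver, Goldman-Hodgkin-Katz calcium influx,
    SWC morphology reading with per-segment diameter variability statistics,
    and summary analyses (integrated calcium, adjacent-branch ratios,
    diameter-pair ratio maps). A synthetic-fixture generator produces
    parametric SWC trees and influx waveforms for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
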