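Package: strutflow
Title: Strut Protrusion and Wall Shear Stress Analysis for Bioresorbable Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for assessing the hemodynamic footprint of
    bioresorbable coronary scaffolds. Generates synthetic vessel phantoms,
    OCT-style pullbacks and biplane angiographic projections with known ground
    truth; quantifies per-strut protrusion and apposition from lumen contours;
    reconstructs a 3D luminal centerline from two projections and mounts
    contours onto it; solves steady incompressible Newtonian flow in an
    axisymmetric finite-volume model with scaffold struts as immersed
    rectangular obstacles; extracts endothelial shear stress (ESS), bins it
    into 5-degree sectors by 200 micron axial intervals with low (< 1 Pa) and
    very-low (< 0.5 Pa) classification; and compares scaffold designs with
    nested linear mixed-effects models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
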