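Package: kneedrill
Title: Virtual Femoral Tunnel Drilling for Transportal ACL Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates femoral tunnel drilling for single-bundle anterior
    cruciate ligament (ACL) reconstruction with the transportal (medial
    portal) technique on triangulated knee bone models. Localizes femoral
    and tibial ACL footprint centers by the quadrant method, poses the knee
    at arbitrary flexion angles about the transepicondylar axis, searches
    for the maximum transverse drill angle (MTA) that clears the medial
    femoral condyle, drills a virtual 8-mm cylinder and measures tunnel
    length, wall breakage (entrance and mid-tunnel) and graft bending angle
    at the femoral aperture across a grid of flexion by drill-angle
    conditions. Includes a seeded parametric generator of synthetic knee
    meshes, repeated-measures ANOVA with Bonferroni post hoc tests and
    Cochran's Q for the resulting cohort tables, and STL/PLY mesh input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
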