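Package: glenovol
Title: Periprosthetic Joint Volume and Impingement-Limited Range of Motion
    in Reverse Shoulder Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the free periprosthetic joint volume around a
    reverse-shoulder-arthroplasty glenosphere and the bony-impingement-limited
    range of motion, as functions of glenosphere design (diameter,
    lateralization, inferior eccentricity).  Provides triangle-mesh geometry
    primitives with Monte Carlo volumetrics, a quadrant decomposition of the
    joint space (anteroinferior, posteroinferior, anterosuperior,
    posterosuperior), a posable simplified humeral component with collision
    detection for adduction and elbow-at-side rotation sweeps, Monte Carlo
    permutation versions of the Mann-Whitney and Kruskal-Wallis tests,
    volume-gain tables, mobility-threshold detection on volume/mobility
    scatter data, and synthetic scapula and cohort generators emulating a
    34-specimen, 7-configuration study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
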