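Package: phalmap
Title: Cortical Bone Cartography and Cross-Sectional Mechanics of Phalangeal Diaphyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of cortical bone in finger bones
    (phalanges) from paired periosteal/endosteal triangle-mesh surfaces:
    automatic anatomical orientation, shaft extraction, slicing into 97
    cross sections with 50 equiangular semi-landmarks each, unrolled
    cortical-thickness maps and proximodistal thickness profiles,
    cross-sectional geometric properties including the polar second moment
    of area J, longitudinal curvature via the included angle, and
    multivariate comparison of individuals against reference groups by
    principal components analysis, canonical variates analysis, one-sample
    Hotelling T-squared tests and typicality probabilities. A parametric
    synthetic phalanx generator with a known ground-truth thickness field
    supports validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, grDevices, graphics, jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr, png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
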