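Package: plaquevuln
Title: Morphological and Stress-Based Vulnerability Indices for Coronary
    Plaque Cross-Sections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative vulnerability assessment of
    atherosclerotic coronary plaque from segmented cross-sectional
    contours (lumen, outer wall, lipid-rich necrotic cores,
    calcifications).  Extracts per-slice morphology (nodal wall and
    fibrous-cap thickness on 100 lumen points in four quarters, minimum
    cap thickness, lipid percentage), assigns ordinal 0-4 cap, lipid,
    morphological and stress vulnerability indices, calibrates stress
    cut-points by exact agreement maximization against the morphological
    index, computes a physically motivated wall-stress and shear-stress
    surrogate built on an anisotropic modified Mooney-Rivlin material
    model, and performs clustered correlation analysis with linear
    mixed-effects models (random intercept per patient).  Includes a
    seeded synthetic-cohort generator producing multi-patient sets of
    vessel cross-sections with controlled cap thickness and lipid burden.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
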