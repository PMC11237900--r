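Package: lrasym
Title: Left-Right Asymmetry Analysis of Posture, Stretch Resistance and
    Lateralized Gene Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of left-right side-specific effects of
    unilateral brain injury transmitted through humoral signaling.
    Implements hindlimb postural asymmetry metrics (PAS, MPA, P_A) with
    robust Bayesian group models and contrast-of-contrasts inference,
    LOESS-smoothed stretch-force work integration with left/right and
    contralesional/ipsilesional asymmetry indices, qPCR reference-gene
    normalization with geNorm stability measures, fold-change and
    lateralization (log2 L/R asymmetry index) statistics, and left/right
    dominant gene co-expression network analysis with permutation
    inference coordinating the hypothalamus and spinal cord. A seeded
    synthetic-data generator reproduces the statistical structure the
    analyses assume so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    rjags,
    coda,
    readxl,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
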