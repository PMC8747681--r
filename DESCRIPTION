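Package: grainpheno
Title: Wheat Grain Image Phenotyping and Seed Storage Trend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying wheat grain morphology and seed coat color
    from photographs of grains scattered on a white background, and for testing
    whether those traits drift with seed storage time. Implements chart-based
    color correction, grain segmentation and contour extraction, a 55-trait
    descriptor set (size, shape, and multi-color-space coat color including
    k-means dominant colors), genotype-centered Pearson trend tests with a
    permutation-plus-bootstrap extreme-value decision rule, germination
    correlation analysis with year centering and outlier exclusion, UPGMA
    clustering and canonical variates (LDA) biplots. Includes a synthetic
    image generator with known ground truth so the full pipeline can be
    validated without real photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    png,
    EBImage,
    MASS,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
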