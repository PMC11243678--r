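Package: dunedyn
Title: Coastal Dune Vegetation Dynamics from Landsat Index Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for decade-scale coastal dune vegetation
    dynamics from monthly Landsat-style surface-reflectance scenes:
    QA-bitmask cloud masking and reflectance scaling, SAVI/NDVI
    computation, biannual median compositing, density-category cover
    accounting and change detection, per-pixel Mann-Kendall trend
    mapping, seasonal nonparametric comparisons, and distance-based
    linear modelling (DistLM) with distance-based redundancy analysis
    (dbRDA) for climate attribution. Includes a synthetic scene
    generator with ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    nortest,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
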