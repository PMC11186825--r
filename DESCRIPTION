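Package: retorg
Title: Phase-Resolved OCT Optoretinography Signal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for optoretinography (ORG) based on
    phase-resolved optical coherence tomography. Provides phase-restoring
    subpixel motion correction of complex B-scan time series, outer-retina
    layer segmentation by shortest-path dynamic programming, self-referenced
    temporal phase extraction with conversion to optical-path-length changes,
    unsupervised discovery (PCA, distance-based outlier removal, Ward
    clustering) and supervised classification (Gaussian-kernel SVM) of
    photoreceptor outer-segment (Type-I) and retinal-pigment-epithelium
    (Type-II) signals in a spatiotemporal feature space, and downstream
    quantification: subretinal-space composition, amplitude/latency/slope
    metrics, en-face functional maps, and rhodopsin bleach-level conversion.
    Includes a synthetic-data module that generates complex OCT B-scan and
    volume series, and phase-trace tables, with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
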