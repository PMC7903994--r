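Package: oncoatlas
Title: Oncogenic Expression Atlas of iPSC-Derived Cardiomyocyte Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as a tested pipeline over seeded synthetic droplet
    data, a single-cell analysis of cardiac differentiation from human induced
    pluripotent stem cells: percentile-based droplet cell calling, median
    normalization, PCA/k-means discovery and time-ordering of differentiation
    stages, hurdle likelihood-ratio marker detection, oncogene and tumor
    suppressor monotone-trend classification, a stage-profile Spearman
    co-expression network with FDR filtering, and single-cell TNNT2/MYC/TP53
    co-occurrence calls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    cluster,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
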