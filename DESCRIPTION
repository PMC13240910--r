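Package: DeltaSol
Title: Rank-Based Statistical Dissection of Protein Solubility Determinants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts 36 global sequence-derived biochemical descriptors from
    protein sequences (residue frequencies, physicochemical group ratios,
    molecular weight, isoelectric point, Henderson-Hasselbalch net charge,
    Kyte-Doolittle hydropathy, Chou-Fasman secondary-structure propensity
    means, disorder and aggregation proxies), quantifies soluble/insoluble
    class differences with rank-based statistics (Mann-Whitney U,
    Benjamini-Hochberg FDR, Cliff's delta with percentile-bootstrap
    confidence intervals, Hodges-Lehmann shift with rank-inversion intervals,
    tie-aware ROC AUC, Youden's J), filters redundant descriptors by Spearman
    correlation, and builds the untrained composite-delta solubility index
    with robust (median/IQR) scaling. Includes a calibrated synthetic
    sequence generator so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, Classification, StatisticalMethod, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
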