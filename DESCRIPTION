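Package: mimico
Title: Integrative miRNA-mRNA Differential Expression and Inverse-Correlation
    Analysis for Paired Case-Control Microarray Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating microRNA and mRNA expression from paired
    case-control two-color microarray studies. Covers spot-level preprocessing
    (triplicate averaging, local background subtraction, within-array ratio
    distribution normalization, across-array quantile normalization),
    differential expression by Pavlidis template matching and one-class
    t-tests, class-separation diagnostics (hierarchical clustering, K-means,
    PCA, leave-one-out linear classification), overlap of differentially
    expressed genes with conservation-filtered miRNA target maps under an
    inverse-direction filter and magnitude cutoff, per-pair concordance
    tables, and Fisher exact gene-set over-representation over GMT
    collections. Includes a synthetic-data generator that plants known miRNA
    effects and inversely responding target genes so the full pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    ape,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
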