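Package: rewireQTL
Title: Rewiring of Germline eQTL Architecture During Skin Tumor Progression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting how germline control of gene expression is
    rewired as benign and malignant tumors develop in a genetically
    heterogeneous mouse backcross. Implements single-marker eQTL scans with
    minimal-p permutation correction and Storey q-value FDR estimation,
    cis/trans architecture summaries and cross-tissue conservation tests,
    tumor-specific and perturbation (normal-to-tumor fold-change) eQTL
    discovery, same-host papilloma similarity permutation tests, skin-to-tumor
    progression co-expression networks with genome-wide error-rate correlation
    thresholds and clique filtering, array-CGH copy-number calling with
    fraction-of-genome-altered summaries, and SAM-based susceptibility
    candidate gene tables. A synthetic backcross cohort generator with planted
    eQTL architecture provides recoverable ground truth for every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: GeneExpression, GeneticVariability, Network, CopyNumberVariation,
    SystemsBiology
RoxygenNote: 7.3.3
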