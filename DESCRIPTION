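Package: moadecon
Title: Mechanism-of-Action Deconvolution from Transcriptomics, Networks and Chemical Structure
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for deconvoluting the mechanism of action of a
    small molecule from a factorial transcriptomic perturbation experiment.
    Implements per-gene factorial differential expression with within-gene
    family-wise error control and the p* contrast-resolution rule, ortholog
    mapping with expansion/averaging, gene-set over-representation with
    cross-condition overlap coefficients and disease-list Fisher tests,
    transcription-factor and pathway activity scoring, causal reasoning on
    signed protein-protein interaction networks (hypothesis scoring to path
    length 5, consensus nodes, concordant subnetwork reconstruction, ensemble
    pooling), similarity-based ligand-target prediction with applicability
    domain estimates, and three-stream evidence integration. A synthetic-data
    generator with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, Network, Pathways, DifferentialExpression, SystemsBiology
RoxygenNote: 7.3.3
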