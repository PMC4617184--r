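Package: sygnet
Title: Systems Genetics of Obesity: eQTL Mapping and Co-Expression Network
    Integration in an F2 Intercross
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative systems-genetics pipeline for selectively profiled
    F2 intercross studies of obesity. Simulates a complete F2 study (divergent
    founder breeds, recombination under the Haldane map, a heritable aggregate
    Obesity Index, negative-binomial adipose expression counts with planted
    cis/trans eQTLs, obesity-associated genes and correlated gene modules),
    and analyses it end to end: count filtering and normalization (median-of-
    ratios size factors, voom-style variance stabilization, quantile/z
    normalization, principal-component removal), per-gene linear modelling of
    expression on the continuous Obesity Index with empirical-Bayes moderated
    statistics, cis/trans eQTL mapping by rank association with permutation-
    based FDR control, supervised weighted co-expression network analysis
    (soft thresholding, topological overlap, module eigengenes, module-trait
    relationships, hub genes), and integration of eQTLs and protein-protein
    interactions with module networks (hypergeometric overlap, betweenness
    centrality, community clustering).
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
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, Genetics, Network, SystemsBiology, Transcriptomics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'coexpression.R'
    'de.R'
    'eqtl.R'
    'integration.R'
    'io.R'
    'preprocess.R'
    'simulate.R'
    'utils.R'
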