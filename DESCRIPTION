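Package: threeCA
Title: Three-Component Analysis for Paired Longitudinal Omics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Vector-based ranking of features measured in paired longitudinal
    designs (the same subject sampled at two time points). Each feature's
    subject pairs are placed as points in an early-vs-late intensity plane and
    summarised by three components: the inter-individual variance radius, the
    signal-strength centroid norm, and the signed perpendicular temporal
    distance from the 45-degree identity line. Equal-weight rank aggregation
    of the three components yields a single score (lower = more significant),
    with a standard-deviation-based selection rule and an inverse-rank
    component-contribution diagnostic. Includes a self-contained pre-ranked
    gene set enrichment analysis (weighted Kolmogorov-Smirnov statistic with a
    gene-permutation null, NES and FDR), baseline paired statistics
    (intra- vs inter-individual change tests with FDR control, Fisher
    over-representation), tiling-array window binning with a quantile floor
    rule and CpG-island shore distance stratification, and a synthetic
    paired-design data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    BiocGenerics,
    rtracklayer,
    limma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
biocViews: GeneExpression, Epigenetics, Transcriptomics, TimeCourse,
    GeneSetEnrichment, Ranking, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
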