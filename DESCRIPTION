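Package: methexpr
Title: Genome-Wide Association of DNA Methylation with Gene Expression
Version: 1.0.0
Authors@R: person("methexpr", "developers", role = c("aut", "cre"),
    email = "devel@methexpr.invalid")
Description: Correlates whole-genome bisulfite sequencing methylation calls
    (CG, CHG and CHH contexts, CGmap format with converters from Bismark,
    BSMAP, methylpy and METHimpute outputs) with gene expression tables.
    Single-methylome analyses cover Pearson/Spearman correlation, ordinal
    (rank-based) association with moving-average smoothing,
    expression-quantile grouping statistics and metagene profiles around
    gene bodies, TSS and TES. Multiple-methylome analyses compare two
    sample groups per gene (methylation difference versus log2 expression
    fold change), call differential genes as low-density outliers of a
    bivariate Gaussian mixture, and cluster joint
    methylome-transcriptome heatmaps. A synthetic-fixture generator with
    planted methylation-expression coupling and a command-line interface
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
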