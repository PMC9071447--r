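Package: axisland
Title: Island and Desert Analysis of Meiotic Chromosome-Axis ChIP-Seq Signal
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Segments a genome into islands of chromosome-axis protein
    enrichment and intervening deserts from a binned ChIP-seq
    fold-enrichment track, and characterises the two region classes:
    region-level signal and feature statistics with nonparametric and
    Welch tests, anchor-centered and gene-scaled signal profiles with
    percentile-bootstrap confidence intervals, gene-pair and intergenic
    classification (convergent, tandem, divergent), coding density and
    GC content, and a logistic model predicting island identity from
    local coding density with ROC/AUC evaluation. A synthetic-data
    generator with planted island/desert truth makes every stage
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: ChIPSeq, Epigenetics, Coverage, Sequencing, Classification
RoxygenNote: 7.3.3
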