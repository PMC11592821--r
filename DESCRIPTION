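Package: covasym
Title: Kinase Fusion Prediction from RNA-Seq Exon Coverage Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts oncogenic tyrosine-kinase gene fusions (ALK by default)
    from whole-transcriptome or targeted RNA-seq alignments without requiring
    junction reads. Computes strand-aware, filtered, exon-length- and
    library-size-normalized per-exon coverage of a target gene, compares
    5'-end (pre-kinase) against kinase-domain exon coverage with an exact
    one-sided permutation Mann-Whitney U test, and gates calls on a
    kinase-domain depth reliability threshold. Includes a deterministic
    stranded-read simulator, a sequencing-depth subsampling experiment for
    calibrating the reliability gate, batch screening over sample manifests,
    coverage plots, and diagnostic confusion metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
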