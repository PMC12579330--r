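Package: sporescope
Title: Morphometry, Flow-Cytometry Genome Sizing and Permutation
    Statistics for Grass-Endophyte Symbioses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for characterizing Epichloe-grass endophyte symbioses
    from laboratory data. Detects and measures asexual reproductive
    structures (conidia, conidiophores) in calibrated micrographs,
    including projected conidial area; calls fluorescence peaks in flow
    cytometry histograms and estimates genome size and ploidy against
    internal reference standards with event-count and CV quality gates;
    implements distance-based PERMANOVA, pairwise permutation tests with
    Holm-Bonferroni adjustment, PCA, linear discriminant analysis with
    leave-one-out cross-validation, Tukey HSD letter displays and colony
    growth rates; summarizes variable and parsimony-informative sites and
    calls polymorphisms in DNA multiple alignments; and generates seeded
    synthetic micrographs, histograms and morphometric tables with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    Biostrings,
    signal,
    igraph,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
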