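Package: CNVeff
Title: Multilevel Gene Expression Efficiency Analysis for CNV-Containing Lineages
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies changes in gene expression efficiency at the
    transcriptional, translational and protein levels between evolved
    strains carrying copy-number variants (CNVs) and their ancestor.
    Implements a copy-number-scaled expected-expression null with a
    negative-binomial Wald test for transcription efficiency, Fisher's
    exact test on TPM-normalized RPF/RNA ratios for translation
    efficiency, a scale-independent transformed near-neighbor test
    (TNNT) combined with a Gaussian-GLM outlier test (TNNTg) for protein
    expression efficiency, a ribosome-profiling uORF caller calibrated
    against a shuffled-triplet null, and Ssd1 CNYUCNYU motif scanning
    with enrichment and co-occurrence tests. Ships a seeded synthetic
    data generator with ground-truth labels so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
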