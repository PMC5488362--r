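Package: psiprior
Title: Bayesian Exon-Inclusion Quantification for Single-Cell RNA-Seq with
    Sequence-Informed Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies exon-skipping splicing (percent spliced-in, PSI) in
    single-cell RNA-seq by combining a mixture-of-isoforms read likelihood with
    an informative prior learned by Bayesian ridge regression of logit-PSI on
    sequence-derived features. Events are extracted from gene annotation and
    filtered by quality rules; 735 regulatory features (lengths, splice-site
    position-weight-matrix strengths, conservation, k-mer frequencies) are
    computed per event; posterior inference uses an adaptive Metropolis-Hastings
    sampler with collapsed regression updates and Geweke convergence
    diagnostics; differential splicing between cells or groups is detected with
    relaxed Savage-Dickey Bayes factors. A simulator reproduces coverage,
    differential-splicing and drop-out benchmark designs, so the whole pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
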