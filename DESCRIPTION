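Package: tomload
Title: Mutational-Load Analysis Through Crop Domestication History
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the burden of deleterious derived alleles carried by
    individual genomes across wild, semi-domesticated and domesticated
    populations. Starting from a multi-sample VCF with an outgroup accession,
    sites are filtered, polarized into ancestral/derived states, and assigned
    to functional categories by intersecting SIFT-style and PROVEAN-style
    effect annotations. The package computes per-genome load counts
    (heterozygotes counted one half), nonsynonymous/synonymous and
    deleterious/neutral-nonsynonymous ratios, population site-frequency
    spectra and derived-allele-frequency comparisons, private-allele
    accounting, windowed nucleotide diversity and Tajima's D, recombination
    and sweep-statistic correlates of load, and a three-caller structural
    variant consensus with gene-feature overlap analysis. A forward
    Wright-Fisher simulator with purifying selection, selfing and bottlenecks
    generates every pipeline input synthetically for testing and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    VariantAnnotation,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
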