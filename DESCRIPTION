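Package: graphpop
Title: Variation-Graph References, Haplotype-Aware Read Simulation and
    Mapping Evaluation for Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds population-augmented variation-graph references from a
    linear backbone and allele-frequency-prioritized variant panels, simulates
    phased diploid populations with controlled site-frequency spectra,
    generates haplotype-aware paired-end short reads with full truth
    annotation, maps reads to linear, consensus and graph references with a
    deterministic seed-and-extend aligner (surjecting graph alignments onto
    linear coordinates), genotypes sites from pileups, and computes the
    evaluation statistics used in graph-reference studies: mapping-error
    rates, pseudo-ROC curves parameterized on mapping quality, reference
    allele bias profiles by variant length, and genotype concordance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    S4Vectors,
    ggplot2,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
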