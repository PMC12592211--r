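Package: uvsdr
Title: Discovery and Evolutionary Analysis of U/V Sex-Determining Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for finding and characterizing U/V
    sex chromosomes in haploid-dioicous organisms such as brown algae.
    Implements k-mer subtraction (YGS-style) scoring of reference windows
    against opposite-sex reads, read-depth sex-linkage classification,
    population statistics for sex-linked scaffolds (sex-biased
    heterozygosity, Weir-Cockerham FST), gametologue pairing with NG86
    Ka/Ks on codon alignments, birth-death ancestral reconstruction of
    sex-determining-region gene content with gain-mechanism
    classification, phylostratigraphic gene ages, and the enrichment
    statistics used to contrast genomic compartments. A synthetic-data
    module generates male/female genome pairs, sexed read sets,
    population genotypes, presence/absence matrices and homology tables
    with known ground truth, so the full pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
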