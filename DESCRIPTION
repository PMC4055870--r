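Package: rDNAphylo
Title: Intraspecies Phylogenetics from rDNA Sequence Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts intragenomic ribosomal DNA sequence heterogeneity
    (SNPs and partial SNPs with occupancy values) into allele-frequency
    matrices for intraspecies phylogenetic inference. Provides a
    concerted-evolution simulator for tandem rDNA arrays (Moran-process
    homogenization, hybridization, read sampling), a base-count variant
    caller with occupancy estimation, Cavalli-Sforza-Edwards chord
    distances, neighbor-joining trees with site-bootstrap supports,
    split-distance tree comparison with a random-topology null, the
    permutation Mantel test, a coverage-based rDNA copy-number estimator,
    and a pSNP-occupancy-based genome-mosaicism classifier.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
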