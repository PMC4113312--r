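Package: esoxsynt
Title: Comparative Genomics, Synteny and Linkage Mapping for a
    Pre-Duplication Esocid Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative-genomic analyses used to evaluate a
    pre-duplication teleost genome: reciprocal-best-hit homologue detection
    with a built-in affine-gap local aligner, percent-identity duplication
    profiles with peak detection, linkage-group-by-chromosome synteny
    matrices with fusion/fission and chimeric-scaffold diagnosis, half-sib
    microsatellite two-point LOD linkage mapping with Kosambi and Haldane
    map functions, and FPKM tissue-specialization scoring. A genome
    evolution simulator (whole-genome duplication, fission, fusion,
    translocation, scaffold fragmentation, half-sib meioses, tissue
    expression) provides fully ground-truthed inputs for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
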