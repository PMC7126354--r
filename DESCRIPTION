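Package: splicecall
Title: Reference-Based Spliced-Alignment Gene Calling for Eukaryotic
    Contigs
Version: 0.1.0
Authors@R:
    person("splicecall", "developers", email = "splicecall@example.org",
           role = c("aut", "cre"))
Description: Discovers protein-coding genes in assembled eukaryotic
    contigs by homology to a reference protein database. Contigs are
    translated in six reading frames into stop-free putative protein
    fragments, fragments are aligned locally to reference targets, and
    the aligned parts (putative exons) are joined into multi-exon gene
    calls by a dynamic program that maximises a composite
    Karlin-Altschul bit-score. Redundant calls from homologous targets
    are clustered, representatives are kept, and same-strand overlaps
    are resolved by E-value. Includes a benchmark harness (annotation
    mapping, exon coverage, precision-recall, inverted-fragment null
    model), identity-based taxonomic assignment, and a synthetic
    genome generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    data.table,
    IRanges,
    methods,
    optparse,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
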