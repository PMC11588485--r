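Package: plastcompare
Title: Comparative Analysis of Annotated Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for comparative plastome analysis: detection of the
    quadripartite structure (LSC/SSC and the inverted-repeat pair) with an
    tabular junction report, perfect microsatellite (SSR) mining and
    classification, codon usage and relative synonymous codon usage (RSCU),
    alignment-based diversity statistics (nucleotide-pair frequencies,
    nucleotide diversity, Tajima's D, indel events and a sequence-variability
    index), divergence-hotspot scanning over homologous CDS and intergenic
    loci, and SNP-based distance phylogenetics (Kimura 2-parameter distances,
    neighbor joining, bootstrap supports).  A synthetic-plastome generator
    with a ground-truth manifest makes every stage testable without external
    downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
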