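Package: nbskit
Title: Comparative Analysis of Plant NBS-LRR Resistance Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide comparative analysis of plant NBS-LRR
    (nucleotide-binding site, leucine-rich repeat) disease resistance gene
    families across related genomes. Classifies protein domain architectures
    (CNL/TNL/NL/CN/TN/N) from motif, coiled-coil and LRR scans; partitions
    gene phylogenies into clades by patristic distance; detects physical
    gene clusters and tandem duplications along scaffolds; identifies
    reciprocal-best-hit orthologs, collinear synteny blocks and conserved
    cluster pairs; computes Nei-Gojobori pairwise dN/dS on codon alignments;
    screens multi-gene alignments for gene conversion with a permutation
    test on identical fragments; and calls gene presence/absence from
    re-sequencing coverage. A synthetic-data generator produces multi-genome
    fixtures with known truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    ape,
    phangorn,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
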