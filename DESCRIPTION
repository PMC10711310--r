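Package: pangsig
Title: Pangenome Partitioning and Phenotype-Group Signatures for Closely Related Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative pangenomics for collections of closely related bacterial
    genomes (isolates and metagenome-assembled genomes) labelled by a host
    phenotype, built around the vaginal Lactobacillus jensenii preterm/full-term
    setting. Clusters proteins into gene families at an identity threshold,
    builds presence/absence matrices, partitions core/shell/cloud and classifies
    pangenome openness by Heaps' law; tests gene-family association with the
    phenotype by Fisher's exact test with multiple-testing correction; scans
    core-gene alignments for group-exclusive amino-acid variants; reconstructs
    core-genome neighbor-joining phylogenies with bootstrap supports; computes
    fragment-based average nucleotide identity with an ANI species gate; and
    profiles marker gene clusters across genomes. A synthetic-pangenome
    generator with planted ground truth makes every stage verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
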