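Package: rnaregulon
Title: Reconstruction and Functional Annotation of Regulons Controlled by
    cis-Regulatory RNA Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative-genomics reconstruction of bacterial regulons
    controlled by cis-regulatory RNA motifs (riboswitches, ribosomal and
    amino acid operon leaders, T-boxes). Infers operons from gene
    annotations using an intergenic-distance rule, assigns covariance-model
    RNA motif hits to target operons through an upstream window anchored at
    the start codon, clusters regulated operons across genomes of a
    taxonomic group into clusters of co-regulated orthologous operons
    (CRONs), scores regulatory conservation, calls T-box amino acid
    specificity from specifier codons in multiple alignments, classifies
    regulated genes into a two-level functional scheme, and computes
    taxonomic distribution and regulon composition statistics. Includes a
    fully specified synthetic-community generator with ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
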