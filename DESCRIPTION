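Package: contigpolish
Title: Compaction, Correction and Quality Assessment of De Novo
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly processing of de novo RNA-Seq contig sets.
    Reduces redundancy (best-transcript-per-locus selection, containment
    removal, greedy overlap merging, multi-set meta merging), corrects
    assembly defects (self-chimera detection and splitting by
    self-alignment, two-pass majority-allele consensus polishing from
    read pileups, multi-ORF chimera splitting, polyA/T and N-stretch
    cleaning), filters contigs by length, coding potential and FPKM, and
    computes assembly quality metrics (N50/L50, mapping rates, protein
    reconstruction, transcript linking, exon-order fidelity). Includes a
    seeded synthetic generator of ground-truthed transcriptomes, reads
    and defect-injected assemblies so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
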