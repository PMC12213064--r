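Package: symbiocode
Title: Genetic Code Inference and Gene-Content Reduction Analysis for
    Endosymbiont Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising extremely reduced bacterial genomes.
    Infers the genetic code of a genome from codons observed at highly
    conserved amino-acid (HCAA) positions of reference marker-protein
    alignments, using a six-frame translated local-alignment search that
    tolerates in-frame stop codons, so that stop-codon reassignments such
    as UGA to tryptophan are detected and an NCBI translation table (11, 4
    or custom) is selected.  Reconstructs a minimal ancestral proteome from
    an orthogroup presence/absence matrix under explicit basal/sister
    criteria and partitions losses into shared and lineage-specific events.
    Includes descriptive genome statistics (GC content, circular GC skew,
    codon usage, feature tallies, tRNA anticodon-stem length) and a
    seed-reproducible synthetic-data generator producing marker families,
    coding genomes under a configurable genetic code, orthogroup matrices
    under a branch-loss model, and tRNAs with prescribed anticodon stems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
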