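Package: mitoboundaries
Title: Probabilistic Refinement of Protein-Coding Gene Boundaries in
    Metazoan Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts precise start and stop codon positions for the 13
    protein-coding genes of metazoan mitochondrial genomes, starting from
    approximate profile-HMM hits.  Candidate boundaries are scored by the
    product of a model-projected distance factor, empirical per-gene
    start/stop codon usage frequencies (including incomplete stop codons
    completed by polyadenylation), and an empirical two-sided gene-length
    p-value, all stratified by NCBI mitochondrial genetic code table.
    Includes the empirical statistics builder that parameterizes the
    predictor, a legacy fixed-window baseline, an annotation comparison
    harness, and a synthetic mitogenome generator for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
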