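Package: tandemdup
Title: Tandem Gene Duplication Detection, Ka/Ks Dating, and Salt-Stress
    Expression Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide analysis of tandem duplicated genes (TDGs):
    detection of tandem pairs and clusters from gene order plus filtered
    protein homology, Nei-Gojobori (1986) Ka/Ks estimation on
    protein-guided codon alignments, dating of duplication events from
    the synonymous-substitution (Ks) distribution via T = Ks/(2*lambda),
    hypergeometric term over-representation with rich factors and
    multi-set comparison, and a time-course tissue-specificity
    classifier for salt-stress expression responses. A synthetic-data
    generator produces genomes with planted tandem arrays, codon pairs
    diverged at known Ka and Ks, planted enriched terms, and a
    two-tissue time-course expression design with a ground-truth
    manifest, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Software, GeneDuplication, SequenceAnalysis
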