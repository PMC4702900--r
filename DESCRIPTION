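Package: lncseekr
Title: Identification, Naming, Conservation and Functional Annotation of Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A toolkit for calling long non-coding RNAs (lncRNAs) and
    transcripts of uncertain coding potential (TUCPs) from assembled
    transcript models. Implements a four-stage filter cascade (transcript
    length and exon count; strand-specific overlap with known coding,
    pseudogene and small-RNA annotation; ORF-based coding-potential
    classification on a 0-1000 CDS score scale; protein-similarity and
    Pfam-domain evidence filters over BLASTX/HMMER tabular output), locus
    clustering with systematic A-B-C transcript naming, cross-species
    best-hit conservation calls with lineage labelling, and a
    guilt-by-association function predictor combining Pearson co-expression
    edges (BH-corrected) with hypergeometric GO enrichment (Bonferroni and
    BH). A seeded synthetic-fixture generator produces toy genomes,
    annotation, hit tables and expression matrices with known truth so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
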