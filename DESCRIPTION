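Package: toxannot
Title: Toxin Gene Annotation in Genomes of Venomous Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated annotation of toxin genes in genome assemblies of
    venomous lineages. Detects putative toxin loci by seed-and-extend
    similarity search against a database of full-length toxin coding
    sequences, chains local hits into candidate loci, selects loci matching
    full-length CDSs, builds exon/intron gene models by spliced alignment
    with canonical ATG starts, stop codons and GT..AG splice sites, and
    classifies annotations as reliable or warning (premature in-frame stop,
    i.e. candidate truncated paralogs or pseudogenes). Includes screening of
    assembled venom-tissue transcripts to build custom toxin databases,
    greedy identity clustering of databases, evaluation metrics (per-family
    toxin recovery rate, automatic and supervised annotation precision), and
    a deterministic synthetic-fixture generator with machine-readable truth
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
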