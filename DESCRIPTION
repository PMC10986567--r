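Package: yeastannot
Title: Reference-Guided Annotation, Gene Families, and Pangenome
    Statistics for Yeast Genome Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-step protein-coding gene annotation pipeline for
    Saccharomyces cerevisiae genome assemblies (homology transfer of
    reference gene models with codon repair, followed by ORF-based
    backfill on masked regions), together with multi-cutoff
    single-linkage protein family clustering, marker-gene based genome
    completeness and base-quality evaluation, pangenome core/accessory
    classification, and rank-based comparison of homolog counts between
    strain groups.  Includes a synthetic genome simulator with ground
    truth tables so every stage can be validated offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
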