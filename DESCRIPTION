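Package: spliceptide
Title: Proteogenomic Detection of Alternative Splicing Events in Shotgun Proteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds custom protein search databases from alternative-splicing
    events applied to reference transcript models (exon skipping, alternative
    3'/5' splice sites, intron retention, and combinations), translating the
    largest ATG-initiated open reading frame of each variant mRNA and tagging
    records with their event provenance. Digests proteins in silico with
    trypsin (no proline restriction, configurable missed cleavages), indexes
    the reference tryptic-peptide universe, and classifies externally
    identified peptides as supporting splicing events when they are unique to
    variant entries. Variant proteins initiating at an alternative translation
    start are further classified into downstream, start-disrupted, and
    upstream categories, with first-ATG-downstream and amino-terminal-isoform
    flags, frequency tables, and annotated global alignment reports. A seeded
    synthetic gene/event/peptide simulator with independent ground truth makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
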