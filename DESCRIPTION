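Package: proteoseed
Title: Proteogenomic Re-Annotation of Bacterial Genomes from Peptide Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds six-frame stop-to-stop open reading frame (ORF) databases
    from bacterial genomes, maps peptide-spectrum-match evidence onto genomic
    coordinates, and classifies structural annotation errors: novel genes in
    unannotated regions, wrongly called coding sequences, erroneous start
    codons detected from semi-tryptic N-terminal peptides, and single-base
    sequencing errors that split a coding region across two reading frames.
    Corrections can be propagated to related genomes through a translated
    homology search with start-codon consensus logic. A synthetic-data
    generator plants each error class in toy genomes with a machine-readable
    ground-truth ledger, so the whole pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
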