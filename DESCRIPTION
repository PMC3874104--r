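Package: lincscreen
Title: Candidate Selection, Enrichment and Phenotype Statistics for
    lincRNA Knockout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the computational stages of a multi-strain lincRNA
    knockout screen: coding-potential filtering of candidate loci (codon
    substitution frequency thresholds, mass-spectrometry tag filters, and
    the ribosome release score computed over enumerated open reading
    frames), rank-based Mann-Whitney gene-set enrichment with
    Benjamini-Hochberg correction, guilt-by-association functional
    prediction from expression compendia, a bootstrap test for local
    enrichment of differential expression around a deleted locus, and
    Mendelian segregation, penetrance, survival and morphometric group
    statistics. A seeded synthetic-data module generates inputs with the
    statistical structure each stage assumes, so the full pipeline runs
    and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
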