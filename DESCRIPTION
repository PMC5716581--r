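Package: splicefate
Title: Predicting mRNA-Processing Outcomes of Splice-Site and Small Coding
    Mutations in Gene Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting how induced point mutations and small
    deletions are resolved at the mRNA level. Given a genome, a transcript
    model and a mutation in HGVS-like genomic notation, the package
    classifies the lesion (essential splice-site donor/acceptor, exonic
    nonsense, exonic indel), enumerates candidate alternative processing
    outcomes (exon skipping, cryptic donor/acceptor use, intron retention)
    in their observed frequency order, derives the mature mRNA and protein
    for each outcome, locates premature termination codons, and applies the
    50-55 nt last-junction rule to call nonsense-mediated decay escape.
    Also included: position-weight-matrix scanning for exonic splice
    enhancers, a genome-wide exon length mod-3 symmetry analysis with
    chi-squared goodness-of-fit, and a seeded synthetic gene-model generator
    that reproduces the structural features of seven mutant zebrafish lines
    for testing every pipeline stage without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils,
    methods,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
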