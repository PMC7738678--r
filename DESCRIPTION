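Package: runxqa
Title: Comparative Analysis of the RUNX2 Glutamine-Alanine Tandem Repeat
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates the RUNX2 N-terminal glutamine-alanine (QA) tandem
    repeat between its conserved MSDVS and VPRLR flanking motifs, quantifies
    polyQ and polyA run composition with interruption tolerance, computes QA
    ratios and codon-level repeat purity, classifies repeat states (absent,
    proto, primitive, variable), maps their emergence onto dated phylogenies
    by parsimony, and correlates repeat composition with morphometric
    traits. Includes a clade-calibrated synthetic sequence generator and a
    replication-slippage simulator so the whole pipeline is testable without
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
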