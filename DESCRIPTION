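Package: dfdscan
Title: Duplication and Functional Differentiation Scanning on Gene Family Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene duplication events on a rooted gene-family tree by
    last-common-ancestor (LCA) reconciliation against a dated species tree,
    tests each event for the double-gene-phylum retention signature (two
    daughter clades with identical species composition), classifies events as
    likely duplication-plus-functional-differentiation (DFD), recently
    retained, or lossy, and associates them with known whole-genome
    duplication (WGD) events by branch and age interval. Also provides the
    coding-sequence curation rules used to assemble such gene families
    (length and annotation filters, same-locus deduplication, tight-paralog
    collapsing, pseudogenization flags) and a birth-death gene-family
    simulator with episodic WGD doubling and a differentiation lock, so that
    every inference stage can be validated against a known event history.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
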