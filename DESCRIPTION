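Package: acetylodiff
Title: Strain- and Allele-Specific Histone Acetylation Analysis with
    Retroelement Insertion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing histone acetylation (H3K9ac) landscapes
    between two diverged mouse strains and their reciprocal F1 hybrids:
    fold-enrichment based strain-specific peak classification, allele-bias
    calling from SNP-assigned ChIP and mRNA read counts, split-read
    detection of polymorphic retroelement (LINE-1, SINE, LTR) insertions
    from long shotgun reads, position-weight-matrix motif scanning with
    exact score p-values and outgroup-based gain/loss inference,
    permutation tests for interval association, and acetylation
    metaprofiles around short 3' LINE-1 fragments. Includes a synthetic
    genome-pair generator with planted cis/trans acetylation effects,
    insertions, and allele-biased expression, providing a ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
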