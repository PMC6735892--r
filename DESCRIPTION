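Package: cfstools
Title: Quantitative Analysis of Common Fragile Site Interactome and Instability Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calling chromatin-associated interactors of common
    fragile sites (CFSs) from triple-SILAC ChIP-MS protein-group tables
    (MaxQuant proteinGroups.txt dialect), including the two-tier fold-change
    filtering cascade (bait versus IgG majority rule, then replication-stress
    induction), local hypergeometric term-enrichment with Benjamini-Hochberg
    correction, and confidence-filtered functional network assembly.  A
    companion imaging arm provides quantitative image-based cytometry (QIBC):
    nucleus segmentation, DAPI/EdU cell-cycle gating, nuclear focus detection,
    micronucleus counting, object-based colocalization, and a Costes-style
    block-randomization test for pixel colocalization.  Cytogenetic statistics
    cover metaphase break/gap summaries, mitotic DNA synthesis (MiDAS)
    proportions with Wilson intervals, chi-square tests of fragile-locus
    breakage, and unpaired t tests.  Seeded synthetic-data generators emulate
    every input with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    igraph,
    mclust,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
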