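Package: svforest
Title: Random-Forest Pathogenicity Scoring of Exon-Altering Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates exon-altering deletions and duplications with 17
    features capturing gene importance (pLI, LOEUF), coding-sequence
    disruption, evolutionary conservation, expression, and exon structure,
    and scores their pathogenicity with a random forest whose score is the
    fraction of trees voting pathogenic. Includes the curation pipeline used
    to build a rare, size-matched case/control training set
    (reciprocal-overlap deduplication, allele-frequency rarity classes,
    tiered size matching, chromosome-based splits), ROC/AUC evaluation with
    Hanley-McNeil standard errors, and a synthetic annotation-bundle
    generator so that the whole pipeline runs end-to-end without external
    genomic resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
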