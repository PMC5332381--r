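Package: ogfamily
Title: Orthogroup Classification and Evolutionary Analysis of Plant Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify the members of a plant multigene family into
    orthologous groups (OGs) anchored at the monocot/dicot split, from
    all-vs-all protein similarity with reciprocal-best-hit confirmation.
    Includes an exact affine-gap pairwise protein aligner, presence/absence
    count matrices with lineage-loss calling against a species taxonomy,
    conserved-alignment-block selection with neighbor-joining trees,
    bootstrap support and OG-monophyly checks, ZOOPS EM discovery of
    OG-specific N-terminal motifs, subfamily grouping and naming, diagnostic
    classification of novel sequences against a curated reference, and a
    birth-death gene-family simulator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
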