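Package: ethnophylo
Title: Phylogenetic Clustering of Ethnomedicinal Therapeutic Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing whether the species that share a traditional
    therapeutic use are phylogenetically clustered or overdispersed. Binary
    species-by-disease-category efficacy tables are placed on a species-level
    phylogeny and each category is scored with the net relatedness index
    (NRI) and nearest taxon index (NTI): standardized effect sizes of the
    mean pairwise and mean nearest-taxon patristic distances against a
    tip-label permutation null, with rank-based p-values. Includes Newick
    tree handling (parse, prune, patristic distances), species-name
    reconciliation against tree tips, per-clade summary tables, a
    synthetic-data generator (Yule trees plus trait matrices with planted
    clustering or overdispersion) for calibration and power analysis, and
    iTOL annotation export for ring-style visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
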