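Package: redmetrics
Title: Relative Evolutionary Distinctness and EDGE Conservation Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes fair-proportion evolutionary distinctness (ED), the
    EDGE prioritization index under several IUCN extinction-probability
    transformations, and the Relative Evolutionary Distinctness (RED) index
    obtained by recomputing ED on a range-weighted phylogeny in which every
    branch length is divided by the number of occupied grid cells of its
    descendant species. Includes midpoint-sister and random within-genus
    placement of species lacking sequence data over replicate trees,
    rank-concordance validation (Kendall's W, Spearman correlation, top-k
    list overlap), and generators for genus-structured synthetic trees,
    gridded occurrences and threat-status tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
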