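Package: phylocanon
Title: Canonical Forms and Displayed Trees for Weighted Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for explicit rooted phylogenetic networks whose edges carry
    finite sets of positive branch lengths. Provides an extended-Newick dialect
    with hybrid-node tags and length-set syntax, enumeration of the weighted
    trees displayed by a network, reduction to the unique funnel-free canonical
    form by funnel suppression and multiedge merging, verification of the
    no-equally-long-paths (NELP) property with explicit witnesses, wishbone and
    crack enumeration, indistinguishability tests between networks, and
    demonstration implementations of network parsimony and likelihood scores
    computed through displayed trees. All branch lengths are handled as exact
    rationals so that set sums and path-length comparisons are reliable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
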