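Package: mpest
Title: Maximum Pseudo-Likelihood Estimation of Species Trees from Gene Trees
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates a rooted species tree (topology and internal branch
    lengths in coalescent units) from a collection of rooted gene-tree
    topologies by maximizing a pseudo-likelihood built from the multinomial
    distribution of rooted-triple frequencies under the multispecies
    coalescent. Includes exhaustive and nearest-neighbor-interchange searches
    over topology space, a multispecies-coalescent gene-tree simulator, a
    Poisson model of horizontal gene transfer at the triple level, gene-level
    bootstrap with majority-rule-extended consensus supports, and the
    Rannala-Yang per-population coalescent likelihood together with an
    executable demonstration that its joint maximum over branch lengths and
    population sizes does not exist.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
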