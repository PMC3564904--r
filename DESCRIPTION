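Package: polygfate
Title: Phylogenetic Fate Mapping from Polyguanine Somatic Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective cell-lineage analysis from somatic mutations at
    polyguanine (polyG) microsatellite tracts genotyped in single-cell clones.
    Implements triplicate fragment-analysis genotype calling, a diploid
    missing-data-aware genetic distance, molecular-clock conversion between
    distance and mitotic divisions, modified eBURST clustering into clonal
    complexes, permutation-calibrated mutational similarity networks,
    tree-imbalance statistics (N-bar and Colless' index) with a
    randomized-genotype null, NEXUS export for external Bayesian inference,
    and a branching lineage simulator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
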