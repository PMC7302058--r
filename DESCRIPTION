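Package: partcong
Title: Partition Incongruence Tests for Discrete Morphological Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and testing the incongruence between
    character partitions of discrete (cladistic) morphological matrices,
    with an emphasis on craniodental versus postcranial partitions.
    Provides NEXUS input/output with character-set support, dataset
    curation (taxon filtering by missing data, removal of
    parsimony-uninformative characters), bit-parallel Fitch parsimony
    scoring and heuristic tree search with tree-bisection-reconnection
    branch swapping, ensemble consistency and retention indices,
    Robinson-Foulds and matching split distances, the incongruence length
    difference (ILD) and incongruence relationship difference (IRD)
    permutation tests, a character-jackknife test of which partition
    yields trees closest to the total-evidence trees, stratigraphic
    congruence indices (GER, GER*, MSM*, SCI), cross-study summary
    statistics, and a synthetic-data generator for partitioned matrices
    and stratigraphic ranges with controlled congruence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
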