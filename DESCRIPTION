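Package: phylograft
Title: Divide-and-Graft Assembly of Large Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds large species-level chronograms by a three-step
    divide-and-graft strategy: reduce and merge homology clusters of DNA
    sequences, select two exemplar species per genus by weighted distal-pair
    voting, assemble a minimally sparse supermatrix by a greedy knapsack,
    infer and fossil-calibrate a backbone chronogram, decompose it into
    clade-level tasks, infer relative-time clade trees, rescale them to
    backbone ages and graft them back.  Includes a simulation engine for
    replicating empirical datasets (birth-death tree simulation, genus
    assignment, substitution-model fitting and sequence simulation),
    normalized Robinson-Foulds and branch-score tree distances, and a
    branch-smeared dispersal-through-time statistic for area-annotated
    chronograms.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
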