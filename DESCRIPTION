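Package: cnrsets
Title: Common-Neighbor-Rule Analysis and Homogeneous Circuit Detection in Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing directed connectomes with chemical synapses
    and electrical gap junctions. Quantifies the common-neighbor rule (the
    tendency of neuron pairs to be connected in proportion to their number of
    shared neighbors) against degree-preserving and Erdos-Renyi null
    ensembles, decomposes common-neighbor sets into a 21-type role-preserving
    triad taxonomy, detects statistically homogeneous sets by hypergeometric
    testing with a majority rule, localizes them to functional network layers,
    and simulates graded-potential dynamics of the mutually-regulating and
    mutually-regulated circuit types. Includes a synthetic connectome
    generator with planted homogeneous sets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
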