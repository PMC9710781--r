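Package: bioesn
Title: Bio-Instantiated Echo State Networks from Connectome Topology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds echo state network reservoirs whose wiring is dictated
    by an area-level connectome. Provides loading, validation and synthesis
    of weighted directed connectomes; five surrogate connectivity
    conditions (rank-preserving and rank-free biological topology, and
    density-, degree- and fully-connected random controls); connectome
    upscaling to neuron-level reservoirs with interareal weight
    conservation and rule-based intrinsic connectivity; leaky echo state
    network dynamics with pseudoinverse readout training; the Memory
    Capacity and Sequence Recall benchmark tasks with their scoring rules;
    and a replicate/grid-search experiment harness with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
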