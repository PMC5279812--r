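Package: loopsis
Title: DNA Looping Probabilities for Protein-Bound Chains by Sequential
    Importance Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte-Carlo modelling of double-stranded DNA looping in the
    presence of bound proteins. DNA is represented as a discrete semi-flexible
    self-avoiding chain of hard spheres and bound proteins as hard spherical
    protrusions; ensembles are grown by off-lattice sequential importance
    sampling with Rosenbluth-style weights. The package computes looping
    probabilities, the looping-probability ratio F(L) and its long-chain
    plateau, an analytic solid-angle ("eclipse") approximation with a
    terminating-segments flexibility correction, and an enhancer front end
    that translates binding-site layouts (positions in bp, protein radii,
    occupancy) into simulation schedules with helical phasing from DNA
    native twist.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
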