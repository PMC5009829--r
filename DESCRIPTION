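Package: bnreach
Title: Reachability Analysis and State-Feedback Control of Synchronous
    Boolean Networks via the Semi-Tensor Product
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Algebraic analysis of synchronous Boolean networks using the
    semi-tensor product (STP) of matrices. Boolean update rules over the
    sixteen binary logical operators are compiled to structure matrices and
    to the global 2^n x 2^n transition matrix, both by direct state
    enumeration and by the STP product formula. The package classifies
    reachable and non-reachable integrated states from the time transition
    diagram, enumerates the six simplest reachable two-node networks,
    synthesizes state-feedback control laws that make a lifted network
    reachable via the block-doubling construction, and simulates
    trajectories with transient/periodic phase decomposition. Ships a
    worked example: the four-gene major switch of the p53 pathway
    (ATM, p53, Wip1, Mdm2) and its period-6 expression pulse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
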