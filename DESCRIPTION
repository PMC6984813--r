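Package: phystype
Title: Patch-Clamp Trace Analysis and Electrophysiological Cell Typing
Version: 0.1.0
Authors@R: person("BLA", "Ephys Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection and quantification of evoked, unitary and spontaneous
    postsynaptic currents from whole-cell voltage-clamp sweeps; extraction of
    fifteen intrinsic membrane properties from square current-step protocols
    in current clamp; and classification of interneurons by Ward hierarchical
    clustering with a Thorndike cluster-count criterion, validated by a
    cross-validated pruned classification tree and a random forest with
    out-of-bag error, Gini importance and proximity embedding. Ships a
    synthetic-recording generator with known ground truth so every stage of
    the pipeline is testable without raw acquisition files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
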