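Package: noncommnet
Title: Noncommutative Sequential Regulation of Complex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Executable discrete dynamical systems for two noncommutative
    models of biological regulation, together with their combinatorial
    theory.  The ratchet model (activators increment and deactivators
    decrement integer target states up to a threshold, as in
    phosphorylation or neural networks) and the sequestration model
    (regulators move targets into mutually protected compartments, as in
    chromosome folding) are implemented with exact reachability
    enumeration, closed-form and recursive counting laws (poly-Bernoulli
    and lonesum-matrix combinatorics, connected one-coloring counts,
    minimal-sequence recursions, orbit counts), orbit decomposition of the
    configuration space, a universal matrix-operator formulation, and a
    regulator-deletion robustness experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
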