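Package: tropicaleq
Title: Tropical Equilibration and Model Reduction for Mass-Action Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes tropical equilibrations of polynomial (mass-action)
    biochemical reaction networks by solving a finite-domain constraint
    problem over integer concentration orders, using reified
    minimum-with-count constraints, dichotomic domain bisection and
    iterative domain expansion.  Reads reaction networks from SBML
    (Level 2/3) or a plain-text reaction format, computes semi-positive
    conservation laws (P-invariants) of the stoichiometric matrix, groups
    equilibrations into branches, and derives tropically truncated
    systems with fast/slow timescale ordering and detection of conserved
    species pools of the truncated dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
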