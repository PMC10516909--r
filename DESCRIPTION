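Package: gcscan
Title: Growth-Coupled Target Scanning for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies metabolic engineering targets that couple growth to
    product formation in a constraint-based (stoichiometric) metabolic model.
    Given a model, a biomass reaction and a target sink reaction, the scan
    enforces the target flux in equal steps up to a capped maximum, re-solves
    flux balance analysis with a deterministic (parsimonious) secondary
    objective at every step, records per-reaction flux profiles, classifies
    reactions as flux-increasing, flux-decreasing or unaffected, scores
    candidates with a step-weighted factor, and filters deletion candidates
    by single-reaction-deletion essentiality. Includes SBML (Level 3 FBC)
    and COBRA-style JSON model input/output, supplementary-style CSV
    reporting, seeded toy-model fixtures with an independent dense-LP oracle,
    and a full-pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    pracma,
    Matrix,
    jsonlite,
    xml2,
    yaml,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
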