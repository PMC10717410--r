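Package: tastecell
Title: Conductance-Based Modelling of TMC4 Chloride Currents in Taste Bud Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-cell conductance-based model of a posterior-tongue taste
    bud cell carrying a voltage-dependent, calcium-insensitive TMC4 chloride
    current alongside Hodgkin-Huxley sodium and delayed-rectifier potassium
    currents. Simulates current-clamp and voltage-clamp protocols, calibrates
    the model against printed electrophysiological anchors (resting potential,
    holding current, action-potential peak), and analyses traces into the
    field's standard read-outs: current-voltage curves, reversal potentials,
    pharmacological inhibition ratios, spike metrics and firing cycle lengths.
    Also includes the tissue-specificity RPKM screen used to nominate Tmc4 as
    a salt-taste candidate, and seeded synthetic-data generators so every
    analysis stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
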