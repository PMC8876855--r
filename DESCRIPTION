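Package: girktools
Title: Kinetic and Pharmacological Characterization of Peptide-Modulated
    GIRK Channel Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-electrode voltage-clamp (TEVC)
    recordings of G protein-coupled inward-rectifier potassium (GIRK)
    channels under ligand application. Implements the bimolecular binding
    scheme (single-exponential wash-in/wash-out, derivation of the
    association and dissociation rate constants and the affinity kd = EC50),
    ramp current-voltage analysis (reversal potential, chord conductance,
    inward-rectification ratio curves), Hill concentration-response fitting,
    Welch's t-test reporting, and computational validation of peptide
    identity (monoisotopic and average masses with disulfide bridges,
    MALDI-ISD c/z and HCD b/y fragment ladders, in-silico tryptic digestion,
    ppm-tolerance peak matching). A seeded synthetic-data generator produces
    recordings with known ground truth so every analysis stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
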