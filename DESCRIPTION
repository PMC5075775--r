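Package: oligoantigen
Title: Design and Evaluation of LNA/DNA Oligonucleotide Antigens for
    Anti-DNA Antibody Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational chain for designing and evaluating locked nucleic
    acid (LNA) modified oligonucleotide antigens against anti-DNA antibodies.
    Covers sequence design from dinucleotide repeats with secondary-structure
    and GC screens and rule-based LNA placement; nearest-neighbor duplex
    melting-temperature estimation with an additive per-LNA increment;
    protein-nucleic-acid interface metrics on coordinate frames (Shrake-Rupley
    solvent-accessible surface area, buried contact area, switched-cutoff
    nonbonded energies, hydrogen-bond and pi-stacking detection with
    trajectory occupancies); 1:1 Langmuir kinetic modelling of surface plasmon
    resonance sensorgrams with global rate-constant fitting; and plate-level
    ELISA statistics (dispersity, Welch t-test, one-way ANOVA, OLS, boxplot
    conventions). Includes seeded synthetic-data generators for every stage.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
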