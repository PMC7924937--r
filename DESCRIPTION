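Package: HairpinReplicator
Title: Thermodynamics and Replication Kinetics of Cross-Catalytic DNA
    Double-Hairpin Assemblies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing template-directed, ligation-free replication of
    binary sequence information by tRNA-shaped DNA double hairpins under thermal
    oscillations. Provides nearest-neighbor duplex thermodynamics with internal and
    terminal mismatch parameters and mixed Na+/Mg2+ salt correction, two-state
    melting curves and their fitting, exhaustive point-mutant sequence-space
    energy distributions, a closed-form cross-catalytic growth model with joint
    trace fitting and serial-transfer simulation, a cumulative-binomial replication
    fidelity model with per-nucleotide inversion, a mechanistic per-cycle
    simulator of the four-step replication mechanism, and seeded synthetic-data
    generators emulating gel-quantified concentration traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite
biocViews: Software, SequenceMatching, Thermodynamics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
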