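Package: tumorsprout
Title: Agent-Based 3D Simulation of Tumor Growth, Angiogenesis and the
    Tumor Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A seeded, scriptable agent-based model of a solid tumor and its
    microenvironment on a bounded 3D lattice: statechart-driven tumor cells,
    sprouting endothelial cells and cancer-associated fibroblasts coupled to
    diffusing oxygen, VEGF, FGF and HGF fields.  Ships scenario presets
    (no angiogenesis, non-proliferating cells, far vessels, high/low oxygen
    and VEGF secretion) and analyses of the model's emergent behaviors:
    necrotic core formation, brush-border vessel branching, the angiogenic
    switch, and the linear-to-exponential growth phase transition with its
    recovery turning point.  The time-stepping core is compiled (Rcpp); a
    minimal hierarchical statechart engine defines the cell behaviors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
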