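Package: coroflow
Title: Computational Coronary Flow, Microvascular Resistance and Subgroup
    Statistics from Two-View Angiographic Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for model-based assessment of the coronary circulation.
    Reconstructs a three-dimensional axisymmetric rigid lumen from two
    angiographic projections acquired at least 30 degrees apart, computes
    absolute coronary blood flow from invasively measured proximal and distal
    pressures with either a quadratic reduced-order pressure-drop model or a
    steady axisymmetric Navier-Stokes solver, and derives fractional flow
    reserve (FFR), coronary flow reserve (CFR) and absolute coronary
    microvascular resistance (CMVR, Wood units) per physiological state.
    Includes a synthetic cohort generator with known ground-truth microvascular
    resistance and self-consistent pressures, consort-style case-exclusion
    accounting, and a rank-based statistical battery (Shapiro-Wilk gate,
    Mann-Whitney U with exact small-sample p, Kruskal-Wallis, chi-square,
    Welch t, one-way ANOVA, Cohen's d / Hedges' g, Pearson correlation) for
    subgroup comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'stats.R'
    'flow_reduced.R'
    'geometry.R'
    'cohort.R'
    'physiology.R'
    'io.R'
    'cli.R'
    'coroflow-package.R'
    'flow_axisym.R'
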