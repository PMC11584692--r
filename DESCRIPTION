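Package: bmecsim
Title: Mechanistic Multi-Pathway Simulation of Brain Microvascular Endothelial Cell Signaling in Ischemia-Reperfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation model of brain microvascular endothelial
    cell (BMEC) signaling spanning inflammation (TNFR/TLR4-NFkB), growth-factor
    survival signaling (VEGFR, Tie2, FGFR, Wnt), hypoxia sensing (PHD-HIF),
    glucose/ATP metabolism (AMPK), and oxidative stress (succinate-SDH-ROS,
    peroxynitrite, tight junctions). Provides quiescent steady-state construction,
    oxygen-glucose deprivation/reoxygenation (OGD/R) protocol simulation with phase
    handoff, biomarker-based proliferation/damage/cell-function scoring and OGD x
    reoxygenation phenotype grids, Latin hypercube sampling with partial rank
    correlation (PRCC) global sensitivity analysis, virtual-cell cohort generation
    and in-silico target interventions, derivative-free pattern-search calibration,
    a synthetic calibration-data generator, and SBML/YAML/CSV interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    withr,
    methods,
    stats,
    utils,
    deSolve,
    lhs,
    yaml,
    jsonlite,
    xml2,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'network-build.R'
    'rhs.R'
    'simulate.R'
    'quiescence.R'
    'protocols.R'
    'scoring.R'
    'sensitivity.R'
    'cohort.R'
    'calibration.R'
    'synthetic-data.R'
    'fixtures.R'
    'config-io.R'
    'sbml.R'
    'plots.R'
    'cli.R'
    'default-network.R'
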