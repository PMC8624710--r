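Package: franzperm
Title: Franz Diffusion Cell Permeation Analysis for Transdermal Formulations
Version: 0.1.0
Authors@R: person("IVPT", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vitro permeation testing (IVPT) with
    Franz diffusion cells: dilution-corrected cumulative-permeation profiles
    from receptor-phase concentration series, per-cell steady-state flux,
    lag time and permeability coefficient by windowed linear regression,
    membrane drug accumulation, inter-membrane flux ratios and profile
    correlations (human skin vs Strat-M), one-way ANOVA with Tukey HSD
    compact-letter displays, and Ward clustering of penetration profiles.
    Includes a Fickian membrane-diffusion simulator with lag-time kinetics,
    withdrawal/replacement sampling and assay noise, plus dose-equivalence
    arithmetic for ion-pair prodrug formulations.
License: MIT
Encoding: UTF-8
Imports:
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
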