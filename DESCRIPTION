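Package: blockfluct
Title: Spatial Block Analysis of Particle-Number Fluctuations in
    Molecular Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates bulk thermodynamic properties of simple liquids and
    liquid mixtures from finite-size molecular simulations by spatial block
    analysis: particle-number fluctuations are measured in cubic subdomains
    of increasing size, corrected for canonical-ensemble and subdomain
    boundary finite-size effects, and extrapolated to the thermodynamic
    limit.  Provides estimators for the reduced isothermal compressibility
    and finite-size Kirkwood-Buff integrals, weighted regression fits of
    the finite-size scaling models, conversion to isothermal
    compressibilities and chemical-potential derivatives, and integration
    of chemical-potential curves relative to a reference state point.
    Includes a minimal Langevin-thermostatted NVT molecular dynamics engine
    for truncated-and-shifted Lennard-Jones fluids, ideal-gas generators
    with exact closed-form fluctuation laws for validation, and
    extended-XYZ trajectory input/output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
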