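Package: odorisk
Title: Probabilistic Odor Risk Assessment for Excavation of VOC-Contaminated Waste
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Screening-level odor risk assessment for emergency excavation of
    waste contaminated with volatile organic compounds. Implements three-phase
    (solid/water/gas) equilibrium partitioning of VOCs into pore gas, an
    excavation-driven volatilization source term, Gaussian plume dispersion
    under Pasquill atmospheric stability classes A-F, odor activity values and
    Weber-Fechner odor intensities on the six-level scale, Potential Hazard
    Index screening, and Monte Carlo uncertainty propagation yielding
    percentile tables, exceedance probabilities and buffer-distance estimates.
    Ships a synthetic-site generator so the full chain is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
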