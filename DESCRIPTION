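Package: thpn2fix
Title: Pressure-Threshold Detection and Quantification of N2 Fixation in
    Closed-Batch Gas Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the THp_N2fix methodology for sealed, pressurised
    serum-bottle cultivations of hydrogenotrophic, autotrophic,
    diazotrophic methanogens. Computes exact stoichiometric residual-
    pressure thresholds for full headspace gas conversion, detects and
    quantifies biological N2 fixation from pressure time series alone,
    derives uptake and evolution rates (NUR, qN2, HUR, CUR, MER, AUR)
    and carbon mass balances from gas-chromatography compositions, fits
    and applies assay standard curves, and validates everything against
    a mechanistic closed-batch simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
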