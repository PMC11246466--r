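Package: meristemsim
Title: Mass-Spring Simulation of Auxin Patterning in a Growing Floral Meristem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sepal primordium positioning in a growing Arabidopsis
    floral meristem as a two-dimensional polygonal cell tissue. Cell walls are
    mass-spring segments deformed by turgor pressure and grown by rest-length
    extension; cells carry auxin and CUC1 concentrations coupled through
    up-the-gradient polar auxin transport (PIN1 allocation weighted by
    neighbour auxin), CUC1 repression by auxin, and a CUC1-dependent PIN
    sensitivity exponent. Cells divide by a noisy minimal-wall-length rule and
    inherit their chemical state. Genotype presets (wild type, cuc1, drmy1,
    drmy1 cuc1) differ in auxin production noise and CUC1 production, and
    growth-rate presets control wall extensibility. A quantification pipeline
    extracts auxin maxima in the middle ring of the disk, builds circular
    intensity histograms, and scores robustness of primordium positioning by
    the coefficient of variation of angular gaps, with ensemble runners and
    dispersion/mean comparison reports.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    car,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
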