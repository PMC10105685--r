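Package: ip3rkit
Title: Single-Channel and Calcium-Imaging Analysis of IP3 Receptor Gating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolchain for ligand regulation of the
    type-1 inositol 1,4,5-trisphosphate receptor (IP3R1) studied in planar
    lipid bilayers and by confocal calcium imaging. Provides stochastic
    two-state gating simulation and rendering of filtered, noisy
    single/multi-channel current records; half-amplitude threshold
    idealization with dead-time censoring, nPo, channel counting and
    dwell-time statistics; Hill, biphasic (bell-shaped) Hill, linear
    current-voltage and double-Hill fitting of dose-response data; Nernst
    potential and electrochemical driving-force arithmetic for calcium
    feedthrough analysis; a synthetic confocal linescan generator and
    calcium-puff detector with FDHM, rise- and decay-time kinetics; a
    synthetic fluorescence plate-reader assay; and total/free calcium
    conversion for EGTA/BAPTA-buffered recording solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    igraph,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
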