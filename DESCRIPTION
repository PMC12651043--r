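Package: erythrospec
Title: Erythrocyte Cytoarchitectonics Indices and Hemoglobin Ligand-Form
    Spectrophotometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of drug-modified erythrocytes: shape-class
    accounting with transformation indices (TI, RTI, IRTI) from scanning
    electron microscopy counts, three-wavelength Beer-Lambert deconvolution of
    intra-erythrocyte hemoglobin ligand forms (oxy-, deoxy-, methemoglobin),
    band metrics of absorption spectra (Soret, Q-bands, aromatic region), and
    per-condition summaries with Student's t-tests. Includes a synthetic-data
    module that simulates multinomial and Dirichlet-multinomial shape-count
    tables and anchor-consistent noisy absorption spectra, plus small
    chemistry helpers for dose-to-molarity arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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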