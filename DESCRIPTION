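Package: cwqsar
Title: Correlation-Weight QSAR Models from SMILES Attributes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds quantitative structure-activity relationship (QSAR)
    models of the optimal-descriptor family: molecular structure is read
    directly from SMILES strings as single-symbol attributes, connected
    symbol pairs and per-vertex nearest-neighbor codes of the
    hydrogen-suppressed graph, and a correlation weight per attribute is
    optimized by a seeded Monte Carlo coordinate search. Target functions
    based on the index of ideality of correlation (IIC) and the correlation
    intensity index (CII) are supported, together with Las Vegas selection
    of train/calibration/validation splits, a full external-validation
    metric suite (Q2, Q2F1-F3, averaged rm2, Fisher F), a
    statistical-defect applicability domain, multi-run promoter
    interpretation, and a synthetic-data generator with planted ground
    truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
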