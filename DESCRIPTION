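Package: fedgamlss
Title: Federated Generalized Additive Models for Location, Scale and Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits generalized additive models for location, scale and shape
    (GAMLSS) with the Rigby-Stasinopoulos (RS) algorithm, both to pooled data
    and to horizontally partitioned data held on separate nodes. In the
    federated path only additive low-dimensional sufficient statistics
    (weighted cross-products, scalar aggregates and counts) leave each node,
    yet the estimates are identical to those from a pooled fit. Supports the
    normal, Box-Cox Cole-Green and Box-Cox power exponential response
    distributions with linear terms and P-splines, disclosure guards in the
    DataSHIELD style, privacy-preserving anonymized knot ranges, centile
    (percentile) curve estimation and z-scores, and synthetic growth-curve and
    heteroscedastic blood-pressure data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
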