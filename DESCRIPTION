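Package: ela
Title: Extended Liquid Association Analysis of Ecological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens multivariate ecological time series (e.g. monthly OTU
    abundances plus co-measured environmental factors) for locally co-occurring
    pairs with local similarity analysis, then identifies third-party mediator
    variables whose level modulates each pair's correlation using the liquid
    association statistic LA(X;Y|Z) = E(XYZ). Provides rank-based inverse-normal
    normalization, a dynamic-programming local similarity score with a
    theoretical significance approximation validated against permutation,
    permutation tests for liquid association, Storey-style q-values, triplet
    typing into the four mediated-correlation classes, Cytoscape-ready network
    export, and a synthetic community generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
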