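Package: lipidstruct
Title: Structural Comparison of Lipids and Lipidomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Headless toolkit for structural lipidomics. Parses lipid
    shorthand nomenclature into structured species objects, computes
    pairwise structural distances between lipids via maximum common
    subgraph alignment with the Jaccard index, embeds lipids into a
    principal-component structural space, compares whole lipidomes with
    the Hausdorff distance and agglomerative clustering, selects lipids
    that describe study variables by sequential forward selection scored
    with AIC, and provides group statistics and quality-control measures
    including Benford's-law conformance checks on abundance tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
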