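Package: synoptic
Title: Repeated Synoptic Analysis of Stream-Network Solute Chemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing repeated synoptic (spatially extensive,
    near-simultaneous) water-chemistry surveys of nested stream networks.
    Implements three watershed-scale metrics for dissolved solutes such as
    DOC, nitrate and soluble reactive phosphorus: the drainage-area scale at
    which among-site concentration variance collapses (single change point in
    variance with a permutation test), subcatchment leverage (each site's
    percent influence on outlet chemistry under area-proportional runoff),
    and seasonal spatial stability (Spearman rank correlation of site
    concentrations between campaigns). A synthetic stream-network generator
    with patch-structured solute sources, conservative area-weighted routing
    and optional first-order net reaction makes every metric testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
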