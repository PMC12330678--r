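Package: rootpareto
Title: Pareto-Optimality and Cost-Efficiency Analysis of Root System
    Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies the cost-efficiency tradeoff of traced
    two-dimensional root systems. A traced root graph (JSON arborescence
    or RSML) is reduced to its terminals (hypocotyl base plus root tips),
    the satellite (transport-optimal star) and heuristic Steiner
    (cost-optimal) extreme architectures are constructed, and the Pareto
    front of the weighted joint objective alpha * total length +
    (1 - alpha) * travel distance is assembled over an alpha grid. The
    measured architecture is positioned on the front by its scaling
    distance and alpha value and compared against a uniform random
    spanning tree null model. Canonical morphological, geometrical and
    dynamic root traits are extracted, and a parametric generator of
    Arabidopsis-like root systems provides ground-truth fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
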