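Package: clustvalid
Title: Significance and Stability Assessment of Clusterings on Weighted
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Validation of community-detection results on undirected
    weighted networks.  Provides community scoring functions adapted to
    weighted graphs (internal density, conductance, normalized cut, out
    degree fractions, a threshold-integral weighted clustering
    coefficient, modularity), a degree-preserving switching null model
    with maximum-weight and constant-variance weight-transfer rules,
    significance reports comparing clustering scores against the null
    ensemble, a nonparametric vertex bootstrap with edge-weight
    perturbation for cluster stability, partition similarity measures
    (variation of information, Rand and adjusted Rand indices, reduced
    mutual information with exact, analytic and Monte Carlo contingency
    table counting), and a weighted stochastic block model benchmark
    generator with planted communities of tunable strength.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
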