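Package: drgnet
Title: Differential Gene Regulatory Network Analysis on Drug-Sensitivity-Specific Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates cell-line-specific gene regulatory networks that vary
    smoothly with a continuous drug-sensitivity value, using a varying
    coefficient regression model fitted by a Gaussian-kernel-weighted
    recursive (adaptive) elastic net, and identifies gene subnetworks that
    are differentially regulated between drug-sensitive and drug-resistant
    cell lines.  Differential regulation is scored by a topological-overlap
    dissimilarity statistic computed over randomly paired sensitive and
    resistant cell lines, with significance assessed by a permutation test.
    Includes a synthetic-data generator with planted sensitivity-varying
    networks, screening utilities (variance filtering, extreme-group
    definition, top-edge extraction, subnetwork decomposition), and an
    end-to-end pipeline that reads DepMap-dialect expression and drug
    sensitivity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
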