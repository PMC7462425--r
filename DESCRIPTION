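Package: netcomplexity
Title: Random-Walk Complexity of Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Local and global complexity of weighted networks estimated from
    the sample entropy of node-strength time series generated by
    strength-biased random walks. The complexity of each node is obtained by
    removing the node, walking on the reduced network, and comparing the
    entropy of the resulting series with the mean entropies of
    strength-matched Erdos-Renyi (disordered) and ring-lattice (ordered)
    null ensembles whose edge weights are drawn from a kernel density
    estimate of the observed weights. Also provides weighted graph metrics
    (directed weighted clustering, global efficiency), construction of
    functional-connectivity networks from multivariate region time series
    (Pearson correlation, Benjamini-Hochberg edge selection, global-signal
    regression, and abs/pos/neg splits), Watts-Strogatz sweep harnesses,
    and surrogate-based mutual-information statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
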