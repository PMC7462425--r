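#' Weighted local clustering coefficient (directed form)
#'
#' Fagiolo's directed weighted clustering: with `What = W^(1/3)` and
#' `M = What + t(What)`, node m's coefficient is
#' `diag(M %*% M %*% M)[m] / (2 * (d_tot * (d_tot - 1) - 2 * d_recip))`,
#' where `d_tot` is in-degree plus out-degree and `d_recip` the number of
#' reciprocated edges. Symmetric matrices are the special case
#' `d_tot = 2 d`, `d_recip = d`, where it reduces to the familiar
#' geometric-mean triangle intensity. Nodes with a zero denominator (degree
#' below 2) get clustering 0. Weights are expected in `[0, 1]`
#' (correlation weights are); other inputs are rescaled by the maximum
#' weight with a warning.
#'
#' @param net a [weighted_network()].
#' @return named length-n vector of local clustering coefficients.
#' @export
weighted_clustering <- function(net) {
  w <- net$weights
  mx <- max(w)
  if (mx > 1) {
    warnf("weights exceed 1: rescaling by max weight %.4g for clustering", mx)
    w <- w / mx
  }
  what <- w^(1/3)
  M <- what + t(what)
  num <- diag(M %*% M %*% M)
  A <- (w > 0) * 1
  d_tot <- rowSums(A) + colSums(A)
  d_recip <- diag(A %*% A)
  denom <- 2 * (d_tot * (d_tot - 1) - 2 * d_recip)
  out <- ifelse(denom > 0, num / denom, 0)
  setNames(out, net$labels)
}

#' Global efficiency
#'
#' Mean inverse shortest weighted path length over ordered node pairs:
#' `E = 1/(N(N-1)) * sum_{i != j} 1 / l_ij`. Edge lengths are the inverse
#' weights `1/w_ij` (the usual convention for connectivity weights, where
#' a strong connection is a short path) or unit lengths. Unreachable pairs
#' contribute 0. A measure of network integration.
#'
#' @param net a [weighted_network()] with at least 2 nodes.
#' @param length_rule `"inverse-weight"` (default) or `"unit"`.
#' @return scalar efficiency; equals 1 for a complete unit-weight graph.
#' @export
global_efficiency <- function(net, length_rule = c("inverse-weight", "unit")) {
  length_rule <- match.arg(length_rule)
  n <- net$n_nodes
  if (n < 2) stopf("need at least 2 nodes")
  g <- igraph::graph_from_adjacency_matrix(
    net$weights, mode = if (net$directed) "directed" else "undirected",
    weighted = TRUE, diag = FALSE)
  lens <- if (length_rule == "inverse-weight") 1 / igraph::E(g)$weight
          else rep(1, igraph::ecount(g))
  D <- igraph::distances(g, mode = "out", weights = lens)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Integration and segregation metrics of a weighted network
#'
#' Bundles the two measures used alongside the complexity pipeline:
#' summed local clustering (segregation; the sum over nodes is the
#' headline statistic, the mean is also reported) and global efficiency
#' (integration).
#'
#' @inheritParams global_efficiency
#' @return list with `clustering_local`, `clustering_total`,
#'   `clustering_mean`, `efficiency`.
#' @export
graph_metrics <- function(net, length_rule = c("inverse-weight", "unit")) {
  cl <- weighted_clustering(net)
  list(clustering_local = cl,
       clustering_total = sum(cl),
       clustering_mean = mean(cl),
       efficiency = global_efficiency(net, length_rule))
}
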