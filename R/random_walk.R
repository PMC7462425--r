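#' Walk configuration
#'
#' Bundles the parameters of a strength-biased random walk. The default
#' series length of 25,000 steps is the length at which the sample entropy
#' of walk series stabilises (entropy no longer changes appreciably beyond
#' ~23,000 points; see [sampen_length_profile()]).
#'
#' @param n_steps series length T (>= 1).
#' @param n_walkers number of independent walkers K.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param start_rule how start nodes are chosen: uniform over non-isolated
#'   nodes (default), from the stationary distribution, or a fixed node.
#' @param start_node node index or label, required for `"fixed-node"`.
#' @param stuck_rule what a walker does at a node with zero out-strength:
#'   restart uniformly over non-isolated nodes (default, keeps the series
#'   length at T) or raise an error.
#' @return an object of class `walk_config`.
#' @export
walk_config <- function(n_steps = 25000L, n_walkers = 1L, seed = NULL,
                        start_rule = c("uniform-random", "stationary", "fixed-node"),
                        start_node = NULL,
                        stuck_rule = c("restart-uniform", "error")) {
  start_rule <- match.arg(start_rule)
  stuck_rule <- match.arg(stuck_rule)
  if (n_steps < 1) stopf("n_steps must be >= 1")
  if (n_walkers < 1) stopf("n_walkers must be >= 1")
  if (start_rule == "fixed-node" && is.null(start_node))
    stopf("start_rule = 'fixed-node' requires start_node")
  structure(list(n_steps = as.integer(n_steps),
                 n_walkers = as.integer(n_walkers), seed = seed,
                 start_rule = start_rule, start_node = start_node,
                 stuck_rule = stuck_rule),
            class = "walk_config")
}

#' Row-stochastic transition matrix of the biased walk
#'
#' Row i is `w_i. / str_i`: the walker moves from i to j with probability
#' proportional to the weight of the connection. Rows of isolated nodes
#' (zero strength) are left all-zero rather than silently made uniform;
#' the walk simulator's `stuck_rule` decides what happens there.
#'
#' @param net a [weighted_network()].
#' @return an n x n matrix whose nonzero rows sum to 1.
#' @export
transition_matrix <- function(net) {
  w <- net$weights
  s <- rowSums(w)
  p <- w
  nz <- s > 0
  p[nz, ] <- w[nz, , drop = FALSE] / s[nz]
  p
}

#' Simulate strength-biased random walkers
#'
#' Runs K independent walkers for T steps and records, at every step, the
#' strength of the visited node. Hubs (high-strength nodes) appear more
#' often in the series; for undirected networks the empirical visit
#' frequency converges to `str_i / sum(str)`.
#'
#' @param net a [weighted_network()] with at least one edge.
#' @param config a [walk_config()].
#' @return an object of class `walk_series`: list with `series` (K x T
#'   matrix of visited-node strengths), `visited` (K x T matrix of node
#'   indices), `visit_freq` (length-n empirical visit probabilities, sums
#'   to 1), `strength` (the node strength vector used).
#' @export
#' @examples
#' net <- generate_ring(6)
#' ws <- simulate_walk(net, walk_config(n_steps = 100, seed = 1))
#' ws$visit_freq
simulate_walk <- function(net, config = walk_config()) {
  stopifnot(inherits(net, "weighted_network"), inherits(config, "walk_config"))
  str <- rowSums(net$weights)
  alive <- which(str > 0)
  if (length(alive) == 0L) stopf("network has no edges: cannot simulate a walk")
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- config$n_walkers
  starts <- switch(config$start_rule,
    "uniform-random" = alive[sample.int(length(alive), K, replace = TRUE)],
    "stationary" = sample.int(net$n_nodes, K, replace = TRUE,
                              prob = str / sum(str)),
    "fixed-node" = {
      sn <- config$start_node
      if (is.character(sn)) sn <- match(sn, net$labels)
      if (is.na(sn) || sn < 1 || sn > net$n_nodes) stopf("invalid start_node")
      rep(as.integer(sn), K)
    })
  if (config$stuck_rule == "error" && any(str[starts] == 0))
    stopf("walker starts at isolated node %d with stuck_rule = 'error'",
          starts[which(str[starts] == 0)[1L]])
  visited <- simulate_walk_cpp(net$weights, config$n_steps, as.integer(starts),
                               config$stuck_rule == "restart-uniform")
  series <- matrix(str[visited], nrow = K)
  vf <- tabulate(visited, nbins = net$n_nodes) / length(visited)
  structure(list(series = series, visited = visited,
                 visit_freq = setNames(vf, net$labels),
                 strength = str, n_steps = config$n_steps, n_walkers = K),
            class = "walk_series")
}

#' @export
print.walk_series <- function(x, ...) {
  cat(sprintf("<walk_series> %d walker(s) x %d steps over %d nodes\n",
              x$n_walkers, x$n_steps, length(x$visit_freq)))
  invisible(x)
}

#' Analytic stationary distribution of the biased walk
#'
#' For an undirected network the biased walk is reversible and its
#' stationary distribution is `str_i / sum_j str_j`; isolated nodes get
#' probability zero. Directed networks have no such closed form — use the
#' empirical `visit_freq` from [simulate_walk()] instead.
#'
#' @param net an undirected [weighted_network()].
#' @return named probability vector of length n.
#' @export
stationary_distribution <- function(net) {
  if (net$directed)
    stopf("stationary_distribution requires an undirected network; use the empirical visit_freq from simulate_walk() for directed input")
  str <- rowSums(net$weights)
  if (sum(str) == 0) stopf("network has no edges")
  setNames(str / sum(str), net$labels)
}

#' Export walk series to CSV
#'
#' One row per walker, values are the visited-node strengths.
#' @param ws a `walk_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_walk_series <- function(ws, path) {
  utils::write.table(ws$series, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
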