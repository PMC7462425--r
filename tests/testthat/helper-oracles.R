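# Independent reference implementations used to validate the package's
# optimized routines. These deliberately use the most literal computation
# available (full pairwise enumeration, triple loops, Floyd-Warshall) and
# share no code with the package internals.

# Sample entropy by literal template-pair enumeration: build the full
# Chebyshev distance matrix between embedding vectors at dimensions m and
# m + 1 (over the first N - m templates), count matching pairs excluding
# self-matches.
sampen_oracle <- function(x, m, r) {
  nt <- length(x) - m
  cheb <- function(len) {
    d <- matrix(0, nt, nt)
    for (k in 0:(len - 1)) {
      v <- x[(1:nt) + k]
      d <- pmax(d, abs(outer(v, v, "-")))
    }
    d
  }
  B <- sum(cheb(m) <= r) - nt
  A <- sum(cheb(m + 1) <= r) - nt
  if (A <= 0 || B <= 0) NA_real_ else -log(A / B)
}

# Directed weighted clustering by explicit triple summation.
clustering_oracle <- function(w) {
  n <- nrow(w)
  Mh <- w^(1 / 3)
  M <- Mh + t(Mh)
  out <- numeric(n)
  for (v in 1:n) {
    s <- 0
    for (i in 1:n) for (j in 1:n) s <- s + M[v, i] * M[i, j] * M[j, v]
    dtot <- sum(w[v, ] > 0) + sum(w[, v] > 0)
    drec <- sum(w[v, ] > 0 & w[, v] > 0)
    den <- 2 * (dtot * (dtot - 1) - 2 * drec)
    out[v] <- if (den > 0) s / den else 0
  }
  out
}

# Classical binary clustering: closed triangles over connected triples.
binary_clustering_oracle <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (v in 1:n) {
    nb <- which(a[v, ] > 0)
    d <- length(nb)
    if (d < 2) next
    tri <- 0
    for (i in nb) for (j in nb) if (i != j && a[i, j] > 0) tri <- tri + 1
    out[v] <- tri / (d * (d - 1))
  }
  out
}

# All-pairs shortest paths by Floyd-Warshall on inverse-weight lengths;
# returns global efficiency.
efficiency_oracle <- function(w, lengths = c("inverse", "unit")) {
  lengths <- match.arg(lengths)
  n <- nrow(w)
  L <- ifelse(w > 0, if (lengths == "inverse") 1 / w else 1, Inf)
  diag(L) <- 0
  for (k in 1:n) L <- pmin(L, outer(L[, k], L[k, ], "+"))
  off <- L[row(L) != col(L)]
  sum(ifelse(is.finite(off), 1 / off, 0)) / (n * (n - 1))
}

# Benjamini-Hochberg step-up rule executed literally.
bh_reject_oracle <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(n) * q / n)
  rej <- rep(FALSE, n)
  if (length(k)) rej[ord[seq_len(max(k))]] <- TRUE
  rej
}

# Random undirected weighted network fixtures.
random_net <- function(n, p_edge = 0.4, seed = NULL, wmax = 1) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[runif(length(ut)) < p_edge]
  w[on] <- runif(length(on), 0.05, wmax)
  w <- w + t(w)
  weighted_network(w)
}

random_connected_net <- function(n, p_edge = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    net <- random_net(n, p_edge)
    g <- igraph::graph_from_adjacency_matrix(net$weights > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(net)
  }
}

# Uniform(0,1)-weighted versions of the package's graph generators, used
# as reference-state inputs for the complexity self-null checks.
uniform_weighted <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- net$weights
  idx <- which(upper.tri(w) & w > 0)
  w[] <- 0
  w[idx] <- runif(length(idx))
  w <- w + t(w)
  weighted_network(w)
}
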