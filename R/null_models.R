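#' Fit a kernel-density weight sampler
#'
#' Gaussian-kernel density estimate of an observed positive-weight
#' distribution, with normal-reference (Silverman) bandwidth. Sampling is
#' by kernel resampling: pick a source weight uniformly and add Gaussian
#' noise with sd equal to the bandwidth. Negative draws are handled by the
#' support rule: `"truncate-at-zero"` redraws them (default), `"reflect"`
#' mirrors them about zero. All returned samples are strictly positive.
#'
#' @param weights vector of at least 10 strictly positive observed weights
#'   (pool the nonzero entries of the matrix or matrices of interest).
#' @param bandwidth kernel sd; default `bw.nrd0(weights)`.
#' @param support_rule `"truncate-at-zero"` or `"reflect"`.
#' @return object of class `weight_sampler`.
#' @export
fit_weight_sampler <- function(weights,
                               bandwidth = NULL,
                               support_rule = c("truncate-at-zero", "reflect")) {
  support_rule <- match.arg(support_rule)
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stopf("all source weights must be strictly positive and finite")
  if (length(weights) < 10)
    stopf("need at least 10 positive weights to fit a density; with fewer, resample the observed weights directly")
  bw <- bandwidth %||% bw.nrd0(weights)
  if (bw <= 0) bw <- max(1e-8, 1e-3 * mean(weights))  # degenerate: all equal
  # canonical order: sampling depends only on the multiset of weights
  weights <- sort(weights)
  structure(list(source_weights = weights, bandwidth = bw,
                 support_rule = support_rule),
            class = "weight_sampler")
}

#' Draw weights from a fitted sampler
#'
#' @param sampler a [fit_weight_sampler()] object.
#' @param n number of draws.
#' @return numeric vector of n strictly positive weights.
#' @export
sample_weights <- function(sampler, n) {
  stopifnot(inherits(sampler, "weight_sampler"))
  src <- sampler$source_weights
  w <- src[sample.int(length(src), n, replace = TRUE)] +
    rnorm(n, 0, sampler$bandwidth)
  if (sampler$support_rule == "reflect") {
    w <- abs(w)
    w[w == 0] <- sampler$bandwidth * 1e-8
  } else {
    for (iter in 1:1000) {
      bad <- which(w <= 0)
      if (length(bad) == 0L) break
      w[bad] <- src[sample.int(length(src), length(bad), replace = TRUE)] +
        rnorm(length(bad), 0, sampler$bandwidth)
    }
    if (any(w <= 0)) stopf("weight sampler failed to produce positive draws")
  }
  w
}

#' Generate an Erdos-Renyi G(n, M) network with sampled weights
#'
#' Exactly `n_edges` distinct node pairs chosen uniformly at random, each
#' assigned an independent weight from the sampler (or unit weight when
#' `sampler` is `NULL`). The fully disordered reference state of the
#' complexity measure.
#'
#' @param n number of nodes.
#' @param n_edges number of undirected edges, `0 < n_edges <= n(n-1)/2`.
#' @param sampler a [fit_weight_sampler()] or `NULL` for unit weights.
#' @param seed optional integer seed.
#' @return an undirected [weighted_network()].
#' @export
generate_er <- function(n, n_edges, sampler = NULL, seed = NULL) {
  npairs <- n * (n - 1) / 2
  if (n_edges < 1 || n_edges > npairs)
    stopf("n_edges must be in [1, %d]", npairs)
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  idx <- which(upper.tri(w))
  chosen <- idx[sample.int(npairs, n_edges)]
  w[chosen] <- if (is.null(sampler)) 1 else sample_weights(sampler, n_edges)
  w <- w + t(w)
  weighted_network(w)
}

#' Generate a ring-lattice (regular) network with sampled weights
#'
#' Node i is connected to its k/2 nearest neighbours on each side of a
#' ring; every node has degree exactly k. The fully ordered reference
#' state of the complexity measure.
#'
#' @param n number of nodes.
#' @param k even degree, `0 < k < n`.
#' @inheritParams generate_er
#' @return an undirected [weighted_network()].
#' @export
generate_rl <- function(n, k, sampler = NULL, seed = NULL) {
  if (k %% 2 != 0) stopf("ring lattice requires an even degree k (got %d)", k)
  if (k < 2 || k >= n) stopf("need 0 < k < n")
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  for (d in seq_len(k / 2)) {
    i <- seq_len(n)
    j <- ((i - 1 + d) %% n) + 1
    wts <- if (is.null(sampler)) rep(1, n) else sample_weights(sampler, n)
    w[cbind(i, j)] <- wts
    w[cbind(j, i)] <- wts
  }
  weighted_network(w)
}

#' Ring of n nodes with unit weights
#'
#' Convenience wrapper for `generate_rl(n, 2)`.
#' @param n number of nodes (>= 3).
#' @return an undirected [weighted_network()].
#' @export
generate_ring <- function(n) generate_rl(n, 2L)

#' Ring-lattice degree matched to an edge count
#'
#' Nearest even integer (round half up) to the average degree `2 m / n`,
#' clamped to the feasible range `[2, 2 floor((n-1)/2)]`.
#' @param n number of nodes.
#' @param n_edges edge count to match.
#' @return even integer degree.
#' @export
rl_degree <- function(n, n_edges) {
  dbar <- 2 * n_edges / n
  k <- 2L * as.integer(floor(dbar / 2 + 0.5))
  kmax <- 2L * (n - 1L) %/% 2L
  max(2L, min(k, kmax))
}

#' Mean walk-series entropy of a null-network ensemble
#'
#' Generates `ensemble_size` independent ER or ring-lattice networks with
#' the given size and edge count and KDE-sampled weights, runs a biased
#' walk on each, and averages the sample entropies of the strength series.
#' Means are taken over defined entropies only; undefined draws (no
#' template matches) are counted, never silently absorbed. Replicate
#' sub-seeds are derived from `(seed, kind, replicate)` so partial reruns
#' reproduce.
#'
#' @param n nodes per null network.
#' @param n_edges target undirected edge count (ER: exact; RL: matched via
#'   [rl_degree()]).
#' @param sampler a [fit_weight_sampler()].
#' @param kind `"ER"` or `"RL"`.
#' @param ensemble_size networks per ensemble (1,000 at full scale).
#' @param n_steps,n_walkers walk parameters.
#' @param m,r_factor SampEn parameters.
#' @param seed master seed for this ensemble.
#' @return list with `kind`, `H_mean`, `n`, `n_undefined`, `values`.
#' @export
ensemble_entropy <- function(n, n_edges, sampler, kind = c("ER", "RL"),
                             ensemble_size = 1000L, n_steps = 25000L,
                             n_walkers = 1L, m = 2L, r_factor = 0.2,
                             seed = 1L) {
  kind <- match.arg(kind)
  vals <- vapply(seq_len(ensemble_size), function(rep) {
    s <- sub_seed(seed, kind, rep)
    set.seed(s)
    net <- if (kind == "ER") generate_er(n, n_edges, sampler)
           else generate_rl(n, rl_degree(n, n_edges), sampler)
    ws <- simulate_walk(net, walk_config(n_steps = n_steps,
                                         n_walkers = n_walkers))
    walk_sampen(ws, m = m, r_factor = r_factor)$value
  }, 0)
  nd <- sum(is.na(vals))
  if (nd == ensemble_size)
    stopf("every %s null network produced an undefined entropy", kind)
  list(kind = kind, H_mean = mean(vals, na.rm = TRUE),
       n = as.integer(ensemble_size), n_undefined = as.integer(nd),
       values = vals)
}

#' Null-ensemble entropy summary for one removed-node network
#'
#' Convenience wrapper computing both the ER and RL ensemble means.
#'
#' @inheritParams ensemble_entropy
#' @return list with `H_ER`, `H_RL`, `n_ER`, `n_RL`, `n_undefined`.
#' @export
null_ensemble_summary <- function(n, n_edges, sampler, ensemble_size = 1000L,
                                  n_steps = 25000L, n_walkers = 1L, m = 2L,
                                  r_factor = 0.2, seed = 1L) {
  er <- ensemble_entropy(n, n_edges, sampler, "ER", ensemble_size, n_steps,
                         n_walkers, m, r_factor, seed)
  rl <- ensemble_entropy(n, n_edges, sampler, "RL", ensemble_size, n_steps,
                         n_walkers, m, r_factor, seed)
  list(H_ER = er$H_mean, H_RL = rl$H_mean, n_ER = er$n, n_RL = rl$n,
       n_undefined = er$n_undefined + rl$n_undefined)
}
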