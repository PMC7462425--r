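#' Watts-Strogatz small-world network with random weights
#'
#' Starts from a ring lattice (k/2 neighbours per side) and visits each
#' lattice edge once; with probability p the far endpoint is rewired to a
#' uniformly chosen target that is neither the source nor an existing
#' neighbour. Edge count is conserved at `n k / 2`. `p = 0` is the regular
#' lattice, `p = 1` the fully randomised (Erdos-Renyi-like) regime, and
#' intermediate p the small-world regime of high clustering and short
#' paths. Edge weights are drawn uniformly on (0, 1) or from a fitted
#' weight sampler.
#'
#' @param n number of nodes.
#' @param k even mean degree, `k < n`.
#' @param p rewiring probability in `[0, 1]`.
#' @param weight_rule `"uniform-0-1"` (default) or `"from-sampler"`.
#' @param sampler a [fit_weight_sampler()], required for
#'   `"from-sampler"`.
#' @param seed optional integer seed.
#' @return an undirected [weighted_network()].
#' @export
generate_ws <- function(n, k, p, weight_rule = c("uniform-0-1", "from-sampler"),
                        sampler = NULL, seed = NULL) {
  weight_rule <- match.arg(weight_rule)
  if (k %% 2 != 0 || k < 2 || k >= n) stopf("need even k with 0 < k < n")
  if (p < 0 || p > 1) stopf("p must be in [0, 1]")
  if (weight_rule == "from-sampler" && is.null(sampler))
    stopf("weight_rule = 'from-sampler' requires a sampler")
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(FALSE, n, n)
  for (d in seq_len(k / 2)) {
    i <- seq_len(n)
    j <- ((i - 1 + d) %% n) + 1
    adj[cbind(i, j)] <- TRUE; adj[cbind(j, i)] <- TRUE
  }
  for (i in seq_len(n)) {
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      if (runif(1) < p) {
        candidates <- which(!adj[i, ] & seq_len(n) != i)
        candidates <- setdiff(candidates, j)
        if (length(candidates) == 0L) next  # node saturated: keep the edge
        jnew <- candidates[sample.int(length(candidates), 1L)]
        adj[i, j] <- adj[j, i] <- FALSE
        adj[i, jnew] <- adj[jnew, i] <- TRUE
      }
    }
  }
  w <- matrix(0, n, n)
  ut <- which(upper.tri(adj) & adj)
  m <- length(ut)
  w[ut] <- if (weight_rule == "uniform-0-1") runif(m)
           else sample_weights(sampler, m)
  w <- w + t(w)
  weighted_network(w)
}

#' Complexity across the order-disorder spectrum
#'
#' For every combination of mean degree k, rewiring probability p, and
#' replicate: generate a Watts-Strogatz network, run the full
#' [network_complexity()] pipeline, and record the global complexity. The
#' defaults are a desk-scale sweep (n = 50, one walker, 5,000-step series,
#' 50-network ensembles, 5 replicates); full-scale runs (n = 100,
#' 25,000-step series, 1,000-network ensembles) use the same interface
#' with larger values at proportionally larger cost.
#'
#' @param n network size.
#' @param k vector of even mean degrees.
#' @param p vector of rewiring probabilities.
#' @param replicates networks per (k, p) cell.
#' @param n_steps,n_walkers,ensemble_size,m,r_factor pipeline parameters,
#'   see [network_complexity()].
#' @param seed master seed; each cell derives a sub-seed from
#'   `(seed, k, p, replicate)` and is reproducible in isolation.
#' @return object of class `sweep_result`: `rows` (one row per cell:
#'   k, p, replicate, global_complexity, H_full) and `summary`
#'   (mean and sd of C per (k, p)).
#' @export
complexity_sweep <- function(n = 50L, k = c(6L, 10L),
                             p = c(0, 0.05, 0.2, 0.5, 1),
                             replicates = 5L, n_steps = 5000L,
                             n_walkers = 1L, ensemble_size = 50L, m = 2L,
                             r_factor = 0.2, seed = 1L) {
  rows <- list()
  for (kk in k) for (pp in p) for (rep in seq_len(replicates)) {
    cell_seed <- sub_seed(seed, "ws", kk, pp, rep)
    net <- generate_ws(n, kk, pp, seed = cell_seed)
    res <- network_complexity(net, n_steps = n_steps, n_walkers = n_walkers,
                              ensemble_size = ensemble_size, m = m,
                              r_factor = r_factor, seed = cell_seed)
    rows[[length(rows) + 1L]] <-
      data.frame(k = kk, p = pp, replicate = rep,
                 global_complexity = res$global_value, H_full = res$H_full)
  }
  rows <- do.call(rbind, rows)
  summ <- aggregate(global_complexity ~ k + p, data = rows,
                    FUN = function(v) c(mean = mean(v), sd = sd(v)))
  summary_df <- data.frame(k = summ$k, p = summ$p,
                           mean_C = summ$global_complexity[, "mean"],
                           sd_C = summ$global_complexity[, "sd"])
  summary_df <- summary_df[order(summary_df$k, summary_df$p), ]
  structure(list(rows = rows, summary = summary_df),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> mean global complexity by (k, p):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Linear association after percentile-band outlier removal
#'
#' Drops points where either coordinate lies outside its own
#' `[lower, upper]` percentile band, then computes the Pearson
#' correlation with a two-sided t-test and the least-squares line.
#'
#' @param x,y numeric vectors of equal length.
#' @param percentile_band lower/upper percentiles (default `c(5, 95)`);
#'   `NULL` disables outlier removal.
#' @return list with `r`, `p_value`, `slope`, `intercept`, `n_used`.
#' @export
fit_linear <- function(x, y, percentile_band = c(5, 95)) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  keep <- rep(TRUE, length(x))
  if (!is.null(percentile_band)) {
    qx <- quantile(x, percentile_band / 100)
    qy <- quantile(y, percentile_band / 100)
    keep <- x >= qx[1] & x <= qx[2] & y >= qy[1] & y <= qy[2]
  }
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("fewer than 3 points survive outlier removal")
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  slope <- cov(x, y) / var(x)
  list(r = unname(ct$estimate), p_value = ct$p.value, slope = slope,
       intercept = mean(y) - slope * mean(x), n_used = length(x))
}

mi_from_codes <- function(cx, cy, bins) {
  n <- length(cx)
  joint <- tabulate(cx + bins * (cy - 1L), nbins = bins * bins) / n
  px <- tabulate(cx, nbins = bins) / n
  py <- tabulate(cy, nbins = bins) / n
  outer_p <- as.vector(px %o% py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer_p[nz]))
}

#' Mutual information with a shuffle-surrogate Z-score
#'
#' Histogram mutual information (equal-count bins, natural log) between x
#' and y, with significance from a surrogate null: x is randomly shuffled
#' `n_shuffles` times, the MI recomputed for each surrogate, and
#' `Z = (MI_obs - mean(MI_surr)) / sd(MI_surr)`.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_shuffles surrogate count (default 1,000).
#' @param bins number of bins (>= 2); default `ceiling(sqrt(n / 5))`.
#' @param seed optional integer seed for the shuffles.
#' @return list with `mi` (nats), `z_score`, `surrogate_mean`,
#'   `surrogate_sd`, `bins`.
#' @export
mi_with_surrogates <- function(x, y, n_shuffles = 1000L, bins = NULL,
                               seed = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (sd(x) == 0 || sd(y) == 0) {
    warnf("constant input: mutual information is 0")
    return(list(mi = 0, z_score = NA_real_, surrogate_mean = NA_real_,
                surrogate_sd = NA_real_, bins = NA_integer_))
  }
  bins <- as.integer(bins %||% ceiling(sqrt(n / 5)))
  if (bins < 2) stopf("bins must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  code <- function(v) as.integer(ceiling(rank(v, ties.method = "first") *
                                           bins / n))
  cx <- code(x); cy <- code(y)
  mi_obs <- mi_from_codes(cx, cy, bins)
  surr <- vapply(seq_len(n_shuffles), function(s) {
    mi_from_codes(cx[sample.int(n)], cy, bins)
  }, 0)
  list(mi = mi_obs,
       z_score = (mi_obs - mean(surr)) / sd(surr),
       surrogate_mean = mean(surr), surrogate_sd = sd(surr),
       bins = bins)
}
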