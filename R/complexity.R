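#' Local complexity of one node
#'
#' The per-node score
#' `c_i = 100 * p_i * (H_ri - H_ER) * (H_ri - H_RL) / H^2`,
#' where `H_ri` is the walk-series entropy of the network with node i
#' removed, `H_ER` and `H_RL` are the mean entropies of matched
#' Erdos-Renyi and ring-lattice null ensembles, `p_i` is the probability
#' of node i appearing in the intact-network walk series, and `H` is the
#' intact network's walk-series entropy. The score vanishes when the
#' removed-node network looks like either reference state and is applied
#' literally, so it can be negative; `clamp_negative` in
#' [network_complexity()] optionally truncates at zero.
#'
#' @param H_removed entropy of the node-removed network's walk series.
#' @param H_er,H_rl null-ensemble mean entropies.
#' @param p probability of the node in the intact walk series.
#' @param H_full entropy of the intact network's walk series (> 0).
#' @return the local complexity (percent units).
#' @export
#' @examples
#' local_complexity(1.0, 1.4, 0.6, p = 0.05, H_full = 1.2)
local_complexity <- function(H_removed, H_er, H_rl, p, H_full) {
  if (!is.finite(H_full) || H_full <= 0)
    stopf("H_full must be positive: the intact network's walk series was perfectly regular or undefined")
  100 * p * (H_removed - H_er) * (H_removed - H_rl) / H_full^2
}

#' Full local/global complexity pipeline
#'
#' For each node i of the network: remove the node, simulate a
#' strength-biased walk on the reduced network and take the sample entropy
#' of its strength series (`H_removed`); build ER and ring-lattice null
#' ensembles of the same size (n - 1) and the same edge count as the
#' reduced network, with edge weights drawn from a kernel-density estimate
#' of the intact network's nonzero weights, and average their walk-series
#' entropies (`H_ER`, `H_RL`); combine with the node's visit probability
#' `p_i` and the intact network's entropy `H` into the local complexity.
#' The global complexity is the sum of the local complexities in node
#' order.
#'
#' Null ensembles depend on the reduced network only through its size and
#' edge count, so by default nodes whose removal leaves the same edge
#' count share one ensemble (`null_cache = TRUE`); this cuts the dominant
#' cost substantially and leaves results invariant under node relabelling.
#'
#' @param net a [weighted_network()] (every node non-isolated, or a
#'   restart `stuck_rule` in effect).
#' @param n_steps walk-series length (default 25,000).
#' @param n_walkers walkers per series (entropies averaged over walkers).
#' @param ensemble_size null networks per ensemble per node (1,000 at
#'   full scale).
#' @param m,r_factor SampEn parameters.
#' @param p_source `"stationary"` (default; the analytic `str_i/sum(str)`
#'   the walk converges to on undirected networks) or `"empirical"`
#'   (visit frequencies of the intact-network walk).
#' @param seed master seed; every per-node and per-replicate computation
#'   derives its own sub-seed, keyed by node label, so results are
#'   independent of evaluation order.
#' @param null_cache share null ensembles across nodes with equal removed
#'   edge counts.
#' @param clamp_negative truncate negative local complexities at zero.
#' @param on_undefined `"flag"` (default: undefined rows excluded from the
#'   global sum with a warning) or `"error"`.
#' @return object of class `complexity_result`: `local` (named vector,
#'   percent units), `global_value` (= `sum(local)` over defined rows, in
#'   node order), `H_full`, `per_node` (data.frame with columns
#'   node_label, H_removed, H_ER, H_RL, p_i, c_i), `config_echo`.
#' @export
network_complexity <- function(net, n_steps = 25000L, n_walkers = 1L,
                               ensemble_size = 1000L, m = 2L, r_factor = 0.2,
                               p_source = c("stationary", "empirical"),
                               seed = 1L, null_cache = TRUE,
                               clamp_negative = FALSE,
                               on_undefined = c("flag", "error")) {
  p_source <- match.arg(p_source)
  on_undefined <- match.arg(on_undefined)
  stopifnot(inherits(net, "weighted_network"))
  n <- net$n_nodes
  if (n < 3) stopf("need at least 3 nodes")

  # walks are simulated in canonical (label-sorted) node order so that
  # results depend on the labelled network, not on matrix row order
  canonical <- function(x) {
    ord <- order(x$labels)
    weighted_network(x$weights[ord, ord], labels = x$labels[ord],
                     directed = x$directed)
  }

  # intact-network walk: H and (optionally) empirical p_i
  cfg <- walk_config(n_steps = n_steps, n_walkers = n_walkers,
                     seed = sub_seed(seed, "intact"))
  ws_full <- simulate_walk(canonical(net), cfg)
  H_full <- walk_sampen(ws_full, m = m, r_factor = r_factor)$value
  if (is.na(H_full) || H_full <= 0)
    stopf("intact-network walk entropy is undefined or zero; local complexities are not defined")
  p <- if (p_source == "stationary") {
    if (net$directed) ws_full$visit_freq else stationary_distribution(net)
  } else ws_full$visit_freq
  p <- p[net$labels]  # back to input node order

  w_nz <- if (net$directed) net$weights[net$weights > 0] else {
    ut <- net$weights[upper.tri(net$weights)]
    ut[ut > 0]
  }
  sampler <- fit_weight_sampler(w_nz)

  cache <- new.env(parent = emptyenv())
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- net$labels[i]
    net_i <- remove_node(net, i)
    m_i <- edge_count(net_i)
    H_ri <- NA_real_; H_er <- NA_real_; H_rl <- NA_real_
    if (m_i >= 1) {
      set.seed(sub_seed(seed, "removed", lab))
      ws_i <- simulate_walk(canonical(net_i),
                            walk_config(n_steps = n_steps,
                                        n_walkers = n_walkers))
      H_ri <- walk_sampen(ws_i, m = m, r_factor = r_factor)$value
      key <- paste0("m", m_i)
      cached <- get0(key, envir = cache, ifnotfound = NULL)
      nulls <- if (null_cache && !is.null(cached)) cached else {
        ns <- null_ensemble_summary(n - 1L, m_i, sampler,
                                    ensemble_size = ensemble_size,
                                    n_steps = n_steps, n_walkers = n_walkers,
                                    m = m, r_factor = r_factor,
                                    seed = sub_seed(seed, "nulls", m_i))
        if (null_cache) cache[[key]] <- ns
        ns
      }
      H_er <- nulls$H_ER; H_rl <- nulls$H_RL
    }
    c_i <- if (anyNA(c(H_ri, H_er, H_rl))) NA_real_
           else local_complexity(H_ri, H_er, H_rl, p[i], H_full)
    if (!is.na(c_i) && clamp_negative && c_i < 0) c_i <- 0
    rows[[i]] <- data.frame(node_label = lab, H_removed = H_ri, H_ER = H_er,
                            H_RL = H_rl, p_i = unname(p[i]), c_i = c_i,
                            stringsAsFactors = FALSE)
  }
  per_node <- do.call(rbind, rows)
  undef <- is.na(per_node$c_i)
  if (any(undef)) {
    msg <- sprintf("%d node(s) have undefined entropies; global complexity computed over the remaining %d",
                   sum(undef), sum(!undef))
    if (on_undefined == "error") stopf("%s", msg) else warnf("%s", msg)
  }
  local <- setNames(per_node$c_i, per_node$node_label)
  structure(list(local = local,
                 global_value = sum(local[!undef]),
                 H_full = H_full,
                 per_node = per_node,
                 config_echo = list(n_steps = n_steps, n_walkers = n_walkers,
                                    ensemble_size = ensemble_size, m = m,
                                    r_factor = r_factor, p_source = p_source,
                                    seed = seed, null_cache = null_cache,
                                    clamp_negative = clamp_negative)),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("<complexity_result> %d nodes | H = %.4g | global complexity C = %.4g\n",
              nrow(x$per_node), x$H_full, x$global_value))
  cat("top nodes by local complexity:\n")
  ord <- order(-abs(x$local))
  print(head(x$per_node[ord, ], 5), row.names = FALSE)
  invisible(x)
}

#' Complexity of node groups
#'
#' Sums and averages local complexities over a node-to-group assignment
#' (e.g. resting-state networks). Nodes missing from `membership` are
#' assigned to group `"NA"`.
#'
#' @param result a [network_complexity()] result.
#' @param membership named character vector (names = node labels, values =
#'   group labels) or two-column data.frame (node_label, group).
#' @return data.frame with columns `group`, `n_nodes`, `total_complexity`
#'   (the group's summed local complexity), `mean_complexity` (per-area
#'   mean).
#' @export
subnetwork_complexity <- function(result, membership) {
  stopifnot(inherits(result, "complexity_result"))
  if (is.data.frame(membership)) {
    membership <- setNames(as.character(membership[[2L]]),
                           as.character(membership[[1L]]))
  }
  labs <- result$per_node$node_label
  unknown <- setdiff(names(membership), labs)
  if (length(unknown))
    stopf("membership refers to unknown node label(s): %s",
          paste(unknown, collapse = ", "))
  grp <- membership[labs]
  grp[is.na(grp)] <- "NA"
  c_i <- result$local
  keep <- !is.na(c_i)
  if (!all(keep)) warnf("excluding %d node(s) with undefined complexity", sum(!keep))
  agg <- aggregate(list(total_complexity = c_i[keep]),
                   by = list(group = grp[keep]), FUN = sum)
  cnt <- aggregate(list(n_nodes = c_i[keep]),
                   by = list(group = grp[keep]), FUN = length)
  out <- merge(cnt, agg, by = "group")
  out$mean_complexity <- out$total_complexity / out$n_nodes
  out[order(out$group), c("group", "n_nodes", "total_complexity",
                          "mean_complexity")]
}
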