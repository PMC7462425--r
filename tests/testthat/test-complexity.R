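test_that("local complexity follows the product-of-differences form", {
  # vanishes when the removed-node entropy equals either reference mean
  expect_equal(local_complexity(1.4, 1.4, 0.6, p = 0.1, H_full = 1.2), 0)
  expect_equal(local_complexity(0.6, 1.4, 0.6, p = 0.1, H_full = 1.2), 0)
  # hand arithmetic: 100 * 0.05 * (-0.4) * (0.4) / 1.44
  expect_equal(local_complexity(1.0, 1.4, 0.6, p = 0.05, H_full = 1.2),
               -0.4 * 0.4 * 5 / 1.44)
  # sign structure: positive iff H_removed is outside the [H_RL, H_ER] band
  expect_gt(local_complexity(1.6, 1.4, 0.6, p = 0.1, H_full = 1), 0)
  expect_gt(local_complexity(0.4, 1.4, 0.6, p = 0.1, H_full = 1), 0)
  expect_lt(local_complexity(1.0, 1.4, 0.6, p = 0.1, H_full = 1), 0)
  expect_error(local_complexity(1, 1.4, 0.6, 0.1, H_full = 0), "positive")
})

quick_pipeline <- function(net, seed = 11, ...) {
  network_complexity(net, n_steps = 500, ensemble_size = 3, seed = seed, ...)
}

test_that("the pipeline is deterministic and sums local into global exactly", {
  net <- random_connected_net(10, seed = 31)
  a <- quick_pipeline(net)
  b <- quick_pipeline(net)
  expect_identical(a$per_node, b$per_node)
  expect_identical(a$global_value, sum(a$local))
  expect_equal(nrow(a$per_node), 10)
  expect_named(a$per_node,
               c("node_label", "H_removed", "H_ER", "H_RL", "p_i", "c_i"))
  expect_equal(a$per_node$c_i,
               100 * a$per_node$p_i *
                 (a$per_node$H_removed - a$per_node$H_ER) *
                 (a$per_node$H_removed - a$per_node$H_RL) / a$H_full^2)
  expect_equal(sum(a$per_node$p_i), 1, tolerance = 1e-12)
})

test_that("null-ensemble caching does not change results, only cost", {
  net <- random_connected_net(9, seed = 32)
  a <- quick_pipeline(net, null_cache = TRUE)
  b <- quick_pipeline(net, null_cache = FALSE)
  expect_equal(a$per_node, b$per_node)
})

test_that("relabelling nodes permutes local complexities and preserves the global", {
  net <- random_connected_net(8, seed = 33)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  net_p <- weighted_network(net$weights[perm, perm],
                            labels = net$labels[perm])
  a <- quick_pipeline(net)
  b <- quick_pipeline(net_p)
  # walks run in canonical label order, removed-network walks are keyed by
  # node label, null ensembles by edge count, and the weight sampler by the
  # weight multiset, so the result depends only on the labelled network
  expect_equal(b$H_full, a$H_full)
  expect_equal(b$local[net$labels], a$local)
  expect_equal(b$global_value, a$global_value)
})

test_that("negative clamping and undefined handling behave as configured", {
  net <- random_connected_net(10, seed = 34)
  a <- quick_pipeline(net)
  cl <- quick_pipeline(net, clamp_negative = TRUE)
  expect_true(all(cl$local >= 0))
  expect_equal(cl$local[a$local >= 0], a$local[a$local >= 0])
})

test_that("group sums partition the global complexity", {
  net <- random_connected_net(10, seed = 35)
  res <- quick_pipeline(net)
  one_group <- setNames(rep("all", 10), net$labels)
  tab <- subnetwork_complexity(res, one_group)
  expect_equal(tab$total_complexity, res$global_value)
  expect_equal(tab$n_nodes, 10)

  half <- setNames(rep(c("g1", "g2"), each = 5), net$labels)
  tab2 <- subnetwork_complexity(res, half)
  expect_equal(sum(tab2$total_complexity), res$global_value)
  expect_equal(tab2$mean_complexity, tab2$total_complexity / tab2$n_nodes)

  # nodes left out of the membership fall into the "NA" group
  partial <- half[1:6]
  tab3 <- subnetwork_complexity(res, partial)
  expect_true("NA" %in% tab3$group)

  expect_error(subnetwork_complexity(res, c(zzz = "g1")), "unknown")
})
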