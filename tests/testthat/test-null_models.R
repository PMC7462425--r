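test_that("weight sampler reproduces its source distribution", {
  set.seed(1)
  # degenerate source: samples concentrate near the common value
  s_const <- fit_weight_sampler(rep(2.5, 50))
  draws <- sample_weights(s_const, 1e4)
  expect_lt(abs(mean(draws) - 2.5) / 2.5, 0.05)
  expect_true(all(draws > 0))

  src <- runif(1e4)
  s_unif <- fit_weight_sampler(src)
  draws <- sample_weights(s_unif, 1e4)
  # exact mean of the zero-truncated kernel mixture (truncation shifts the
  # mean of a near-zero-supported source slightly upward)
  bw <- s_unif$bandwidth
  m_true <- mean(src * pnorm(src / bw) + bw * dnorm(src / bw)) /
    mean(pnorm(src / bw))
  expect_lt(abs(mean(draws) - m_true), 0.01)
  expect_lt(abs(mean(draws) - 0.5), 0.03)

  expect_error(fit_weight_sampler(c(rep(1, 20), 0)), "positive")
  expect_error(fit_weight_sampler(c(rep(1, 20), -2)), "positive")
  expect_error(fit_weight_sampler(rep(1, 5)), "at least 10")
})

test_that("large samples match the kernel mixture CDF", {
  set.seed(2)
  src <- rnorm(30, mean = 10, sd = 1)  # well away from zero: truncation inert
  sampler <- fit_weight_sampler(src)
  draws <- sample_weights(sampler, 1e5)
  kde_cdf <- function(x) {
    vapply(x, function(xi) mean(pnorm((xi - src) / sampler$bandwidth)), 0)
  }
  xs <- sort(draws)
  emp <- seq_along(xs) / length(xs)
  ks <- max(abs(emp - kde_cdf(xs)))
  expect_lt(ks, 0.02)
})

test_that("ER generator places exactly the requested edges uniformly", {
  sampler <- fit_weight_sampler(runif(50) + 0.5)
  full <- generate_er(4, 6, sampler, seed = 1)
  expect_equal(node_strengths(full)$degree, rep(3L, 4))

  set.seed(3)
  for (i in 1:20) {
    net <- generate_er(30, 60, sampler)
    expect_equal(edge_count(net), 60L)
    expect_true(all(net$weights[net$weights != 0] > 0))
  }
  expect_error(generate_er(5, 11, sampler), "n_edges")

  # degree distribution across realizations ~ Binomial(n-1, M / npairs)
  set.seed(4)
  degs <- unlist(lapply(1:200, function(i)
    node_strengths(generate_er(40, 80, sampler))$degree))
  p_edge <- 80 / choose(40, 2)
  breaks <- c(-Inf, 1, 2, 3, 4, 5, 6, Inf)
  obs <- table(cut(degs, breaks))
  pr <- diff(pbinom(c(-Inf, 1, 2, 3, 4, 5, 6, Inf), 39, p_edge))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr)$p.value), 0.01)
})

test_that("ring lattice is regular with the expected clustering", {
  expect_equal(node_strengths(generate_rl(6, 2))$degree, rep(2L, 6))
  lat <- generate_rl(100, 6)
  expect_equal(node_strengths(lat)$degree, rep(6L, 100))
  expect_equal(edge_count(lat), 300L)
  # closed form 3(k-2) / (4(k-1)) for a k-nearest-neighbour ring
  expect_equal(unname(weighted_clustering(lat)), rep(0.6, 100),
               tolerance = 1e-12)
  expect_error(generate_rl(10, 3), "even")
})

test_that("lattice degree matching rounds the average degree to the nearest even", {
  expect_equal(rl_degree(10, 25), 6L)   # mean degree 5: half rounds up
  expect_equal(rl_degree(10, 24), 4L)   # mean degree 4.8 -> 4
  expect_equal(rl_degree(10, 26), 6L)   # 5.2 -> 6
  expect_equal(rl_degree(20, 5), 2L)    # floor clamp
  expect_equal(rl_degree(5, 10), 4L)    # ceiling clamp at n - 1
})

test_that("ensemble entropy is deterministic and composes from sub-seeded draws", {
  set.seed(5)
  sampler <- fit_weight_sampler(runif(40) + 0.2)
  a <- ensemble_entropy(15, 30, sampler, "ER", ensemble_size = 4,
                        n_steps = 400, seed = 77)
  b <- ensemble_entropy(15, 30, sampler, "ER", ensemble_size = 4,
                        n_steps = 400, seed = 77)
  expect_identical(a$values, b$values)

  single <- ensemble_entropy(15, 30, sampler, "RL", ensemble_size = 1,
                             n_steps = 400, seed = 78)
  set.seed(sub_seed(78, "RL", 1))
  net <- generate_rl(15, rl_degree(15, 30), sampler)
  ws <- simulate_walk(net, walk_config(n_steps = 400))
  expect_equal(single$H_mean, sampen(ws$series[1, ])$value)

  both <- null_ensemble_summary(15, 30, sampler, ensemble_size = 3,
                                n_steps = 400, seed = 79)
  expect_true(is.finite(both$H_ER) && is.finite(both$H_RL))
  expect_equal(both$n_ER + both$n_RL, 6L)
})
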