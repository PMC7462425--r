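test_that("global-signal regression removes the shared component exactly", {
  set.seed(1)
  # all regions identical: residuals vanish
  x <- matrix(rnorm(100), 100, 1)[, rep(1, 5)]
  res <- regress_global_signal(x)
  expect_lt(max(abs(res$data)), 1e-10)

  # residuals are orthogonal to the global signal
  y <- matrix(rnorm(500), 100, 5) + rnorm(100)
  res <- regress_global_signal(y)
  g <- rowMeans(y)
  for (j in 1:5) expect_lt(abs(cor(res$data[, j], g)), 1e-10)

  # two-region closed-form simple regression
  t2 <- cbind(a = rnorm(50), b = rnorm(50))
  g2 <- rowMeans(t2)
  res2 <- regress_global_signal(t2)
  beta <- cov(t2[, 1], g2) / var(g2)
  manual <- t2[, 1] - mean(t2[, 1]) - beta * (g2 - mean(g2))
  expect_equal(unname(res2$data[, 1]), unname(manual), tolerance = 1e-10)
})

test_that("significant correlations are routed by sign into pos/neg/abs", {
  set.seed(2)
  base <- rnorm(200)
  x <- cbind(base, base + rnorm(200, 0, 0.1), -base + rnorm(200, 0, 0.1),
             rnorm(200), rnorm(200))
  cs <- build_connectivity(x, q = 0.05)
  expect_gt(cs$pos_net$weights[1, 2], 0.9)
  expect_equal(cs$neg_net$weights[1, 2], 0)
  expect_gt(cs$neg_net$weights[1, 3], 0.9)
  expect_equal(cs$pos_net$weights[1, 3], 0)
  expect_identical(cs$abs_net$weights,
                   cs$pos_net$weights + cs$neg_net$weights)
  expect_equal(diag(cs$r_matrix), rep(0, 5), ignore_attr = TRUE)
  expect_true(max(abs(cs$r_matrix)) <= 1)
})

test_that("the additive abs = pos + neg contract holds on random constructions", {
  set.seed(3)
  for (rep in 1:25) {
    x <- matrix(rnorm(40 * 8), 40, 8)
    cs <- build_connectivity(x, q = 0.2)
    expect_identical(cs$abs_net$weights,
                     cs$pos_net$weights + cs$neg_net$weights)
    surv <- cs$abs_net$weights != 0
    expect_true(all((cs$q_matrix[surv]) <= 0.2))
  }
})

test_that("edge selection follows the BH step-up rule", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.44, 0.75, 0.9, 0.9)
  # literal step-up: largest i with p_(i) <= i q / n is i = 2
  expect_equal(sum(bh_reject_oracle(p, 0.05)), 2)
  expect_equal(which(bh_reject_oracle(p, 0.05)), c(1, 2))
  # package route (p.adjust) agrees with the oracle on random p-lists
  set.seed(4)
  for (rep in 1:20) {
    pl <- runif(sample(c(10, 100, 1000), 1))^sample(1:3, 1)
    expect_identical(p.adjust(pl, "BH") <= 0.05, bh_reject_oracle(pl, 0.05))
  }
})

test_that("zero-variance regions become isolated nodes, not errors", {
  set.seed(5)
  x <- cbind(matrix(rnorm(300), 100, 3), flat = 1)
  expect_warning(cs <- build_connectivity(x), "zero-variance")
  expect_equal(node_strengths(cs$abs_net)$degree[4], 0L)
})

test_that("synthetic region signals carry the requested correlation structure", {
  ts1 <- synth_roi_signals(10, 4000, block_sizes = c(4, 3), within = 0.6,
                           seed = 6)
  r <- cor(ts1$data)
  expect_lt(max(abs(r[1:4, 1:4][upper.tri(r[1:4, 1:4])] - 0.6)), 3 / sqrt(4000) + 0.05)
  expect_lt(mean(abs(r[1:4, 8:10])), 0.05)

  neg <- synth_roi_signals(6, 2000, negative_pairs = cbind(1, 2),
                           negative_level = -0.5, seed = 7)
  expect_lt(cor(neg$data)[1, 2], -0.35)

  a <- synth_roi_signals(5, 100, block_sizes = 5, within = 0.4, seed = 8)
  b <- synth_roi_signals(5, 100, block_sizes = 5, within = 0.4, seed = 8)
  expect_identical(a$data, b$data)

  # r(1,2) = r(1,3) = 0.9 with r(2,3) = -0.9 is infeasible
  expect_error(synth_roi_signals(3, 50, block_sizes = 3, within = 0.9,
                                 negative_pairs = rbind(c(2, 3)),
                                 negative_level = -0.9),
               "positive semidefinite")
})

test_that("removing a strong global component uncovers negative correlations", {
  ts <- synth_roi_signals(12, 800, block_sizes = c(4, 4), within = 0.5,
                          negative_pairs = rbind(c(1, 5), c(2, 6)),
                          negative_level = -0.4, global_amplitude = 1.5,
                          seed = 9)
  raw <- build_connectivity(ts, q = 0.05, gsr = FALSE)
  gsr <- build_connectivity(ts, q = 0.05, gsr = TRUE)
  expect_gt(gsr$n_edges["neg"], raw$n_edges["neg"])
})
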