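test_that("construction validates, symmetrizes, and strips self-loops", {
  w <- matrix(c(0, 1, 0, 1, 0, 2, 0, 2, 0), 3, 3)
  net <- weighted_network(w, labels = c("a", "b", "c"))
  expect_equal(unname(node_strengths(net)$strength), c(1, 3, 2))
  expect_equal(node_strengths(net)$degree, c(1L, 2L, 1L))

  expect_error(weighted_network(matrix(1, 2, 3)), "square")
  expect_error(weighted_network(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
  expect_error(weighted_network(matrix(c(0, -1, -1, 0), 2, 2)), "negative")

  wl <- w; diag(wl) <- 5
  expect_warning(net2 <- weighted_network(wl), "self-loop")
  expect_equal(net2$weights, net$weights, ignore_attr = TRUE)

  wa <- w; wa[1, 2] <- 1; wa[2, 1] <- 5
  expect_error(weighted_network(wa), "asymmetric")
  expect_silent(weighted_network(wa, directed = TRUE))
})

test_that("matrix-csv and edge-list readers agree and round-trip exactly", {
  f_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,0", "1,0,2", "0,2,0"), f_csv)
  net <- load_network(f_csv, "matrix-csv")
  expect_equal(unname(node_strengths(net)$strength), c(1, 3, 2))

  f_el <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a b 1", "b c 2"), f_el)
  net_el <- load_network(f_el, "edge-list")
  expect_equal(net_el$weights, net$weights, ignore_attr = TRUE)
  expect_equal(net_el$labels, c("a", "b", "c"))

  # full-precision round trip on awkward doubles
  set.seed(7)
  w <- matrix(0, 5, 5)
  w[upper.tri(w)] <- runif(10) * pi
  w <- w + t(w)
  net3 <- weighted_network(w)
  f_rt <- withr::local_tempfile(fileext = ".csv")
  save_network(net3, f_rt)
  back <- load_network(f_rt)
  expect_identical(back$weights, net3$weights)
  expect_identical(back$labels, net3$labels)

  # asymmetric csv rejected for undirected load
  f_bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1", "5,0"), f_bad)
  expect_error(load_network(f_bad), "asymmetric")
  # negative entry named unless absolute = TRUE
  f_neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,-1", "-1,0"), f_neg)
  expect_error(load_network(f_neg), "negative")
  expect_equal(load_network(f_neg, absolute = TRUE)$weights[1, 2], 1)
})

test_that("graphml with weight attribute loads through igraph", {
  net <- random_net(6, seed = 3)
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- net$labels
  f <- withr::local_tempfile(fileext = ".graphml")
  igraph::write_graph(g, f, format = "graphml")
  back <- load_network(f)
  expect_equal(back$weights[net$labels, net$labels], net$weights,
               tolerance = 1e-12)
})

test_that("node removal slices the matrix and preserves the rest", {
  # path a-b-c: removing the middle node leaves no edges
  f <- function(...) matrix(c(...), 3, 3)
  path <- weighted_network(f(0, 1, 0, 1, 0, 1, 0, 1, 0),
                           labels = c("a", "b", "c"))
  cut <- remove_node(path, "b")
  expect_equal(sum(cut$weights), 0)
  expect_equal(cut$labels, c("a", "c"))

  comp5 <- weighted_network(matrix(1, 5, 5) - diag(5))
  expect_equal(remove_node(comp5, 3)$weights,
               matrix(1, 4, 4) - diag(4), ignore_attr = TRUE)

  net <- random_net(8, seed = 11)
  for (i in 1:8) {
    expect_identical(remove_node(net, i)$weights, net$weights[-i, -i])
    # surviving strengths drop by exactly the removed edge weight
    s_before <- node_strengths(net)$strength[-i]
    s_after <- node_strengths(remove_node(net, i))$strength
    expect_equal(unname(s_after), unname(s_before - net$weights[-i, i]))
  }
  expect_error(remove_node(net, 9), "out of range")
})
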