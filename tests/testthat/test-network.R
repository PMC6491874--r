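test_that("pearson matches exact and hand-worked cases", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
  expect_error(pearson(c(1, 2), c(3, 4)), ">= 3")
})

test_that("pearson agrees with the standardized-product formulation", {
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    n <- sample(3:25, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    worst <- max(worst, abs(pearson(x, y) - pearson_bruteforce(x, y)))
  }
  expect_lt(worst, 1e-12)
})

test_that("rank network links each gene to its top correlated neighbors", {
  # two perfectly correlated pairs, cross-correlations near zero
  set.seed(5)
  base1 <- rnorm(30)
  base2 <- rnorm(30)
  m <- toy_matrix(rbind(base1, base1 * 2 + 1, base2, base2 * 3 - 2),
                  genes = c("A", "B", "C", "D"))
  net <- build_rank_network(m, n_neighbors = 1)
  el <- igraph::as_data_frame(net$graph, what = "edges")
  got <- sort(paste(pmin(el$from, el$to), pmax(el$from, el$to)))
  expect_equal(got, c("A B", "C D"))
  expect_equal(el$weight[order(el$from)], c(1, 1), tolerance = 1e-12)
})

test_that("rank network obeys the union-graph degree bounds", {
  set.seed(9)
  m <- toy_matrix(matrix(rnorm(30 * 20), 30, 20))
  for (n_nb in c(2, 4)) {
    net <- build_rank_network(m, n_neighbors = n_nb)
    deg <- igraph::degree(net$graph)
    expect_true(all(deg >= n_nb))
    expect_gte(mean(deg), n_nb)
    expect_lte(mean(deg), 2 * n_nb)
    expect_equal(net$raw_selection_count, 30 * n_nb)
  }
  # n = G - 1 selects everyone: complete graph
  net_full <- build_rank_network(m[1:8, ], n_neighbors = 7)
  expect_equal(net_full$n_edges, choose(8, 2))
})

test_that("rank network is invariant to gene relabeling", {
  set.seed(13)
  m <- toy_matrix(matrix(rnorm(15 * 25), 15, 25))
  net1 <- build_rank_network(m, n_neighbors = 3)
  perm <- sample(nrow(m))
  m2 <- m[perm, ]
  net2 <- build_rank_network(m2, n_neighbors = 3)
  e1 <- igraph::as_data_frame(net1$graph, what = "edges")
  e2 <- igraph::as_data_frame(net2$graph, what = "edges")
  k1 <- paste(pmin(e1$from, e1$to), pmax(e1$from, e1$to))
  k2 <- paste(pmin(e2$from, e2$to), pmax(e2$from, e2$to))
  expect_equal(sort(k1), sort(k2))
  # edge weight symmetric: stored r identical regardless of direction
  expect_equal(e1$weight[order(k1)], e2$weight[order(k2)], tolerance = 1e-12)
})

test_that("zero-variance genes are excluded from the network", {
  set.seed(4)
  m <- toy_matrix(rbind(matrix(rnorm(6 * 10), 6, 10), rep(1, 10)))
  expect_warning(net <- build_rank_network(m, n_neighbors = 2),
                 "zero-variance")
  expect_equal(igraph::vcount(net$graph), 6)
})

test_that("power-law fit recovers exact log-log lines", {
  # frequencies exactly on P(k) = c k^-2: 16, 4, 1 nodes of degree 1, 2, 4.
  # ring of four (degree 2), a hub with four leaves (degrees 4 and 1),
  # six disjoint edges (degree 1): counts 16/4/1.
  edges <- c("a1", "a2", "a2", "a3", "a3", "a4", "a4", "a1",
             "h", "l1", "h", "l2", "h", "l3", "h", "l4",
             rbind(sprintf("p%02d", seq(1, 12, 2)),
                   sprintf("p%02d", seq(2, 12, 2))))
  g <- igraph::make_graph(edges, directed = FALSE)
  stopifnot(identical(as.integer(table(igraph::degree(g))[c("1", "2", "4")]),
                      c(16L, 4L, 1L)))
  fit <- power_law_fit(g)
  expect_equal(fit$correlation, 1, tolerance = 1e-12)
  expect_equal(fit$r_square, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -2, tolerance = 0.05)

  # star graph: two distinct degrees, two points determine a line
  star <- igraph::make_star(6, mode = "undirected")
  fit_star <- power_law_fit(star)
  expect_equal(fit_star$r_square, 1, tolerance = 1e-12)

  ring <- igraph::make_ring(5)
  expect_error(power_law_fit(ring), "distinct degrees")
})
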