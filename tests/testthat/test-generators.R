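test_that("ring lattices have the prescribed regular structure", {
  net <- ring_lattice(100, 4)
  d <- degrees(net)
  expect_true(all(d$degree == 4L))
  expect_equal(d$total_links, 200L)

  c4 <- ring_lattice(4, 2)
  expect_equal(degrees(c4)$total_links, 4L)
  expect_equal(degrees(c4)$degree, rep(2L, 4))

  f <- feature_matrix(ring_lattice(200, 4))
  expect_true(all(abs(f[, "clustering_coeff"] - 0.5) < 1e-12))

  expect_error(ring_lattice(10, 3), "even")
  expect_error(ring_lattice(4, 4), "n > k")
})

test_that("ER graphs hit the requested density on average", {
  expect_equal(degrees(er_random(20, 0, 1))$total_links, 0L)
  expect_equal(degrees(er_random(10, 1, 1))$total_links, choose(10, 2))

  counts <- vapply(1:200, function(s) degrees(er_random(40, 0.25, s))$total_links, 1L)
  expected <- 0.25 * choose(40, 2)                       # 195
  se <- sqrt(choose(40, 2) * 0.25 * 0.75 / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  expect_error(er_random(10, 1.5, 1), "density")
})

test_that("BA graphs have the exact edge count and heavier degree tail than ER", {
  expect_equal(degrees(ba_random(5, 1, 3))$total_links, 4L)
  for (s in 1:5)
    expect_equal(degrees(ba_random(30, 3, s))$total_links,
                 3L * 27L + choose(3, 2))
  expect_error(ba_random(10, 0, 1))
  expect_error(ba_random(10, 10, 1))

  gini <- function(x) {
    x <- sort(x)
    n <- length(x)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
  n <- 60; m <- 2
  ba_edges <- m * (n - m) + choose(m, 2)
  dens <- ba_edges / choose(n, 2)
  g_ba <- mean(vapply(1:50, function(s) gini(degrees(ba_random(n, m, s))$degree), 1))
  g_er <- mean(vapply(1:50, function(s) gini(degrees(er_random(n, dens, s))$degree), 1))
  expect_gt(g_ba, g_er)
})

test_that("WS rewiring preserves edge count and randomises clustering", {
  expect_identical(ws_random(50, 4, 0, 7)$adjacency, ring_lattice(50, 4)$adjacency)
  for (p in c(0.1, 0.5, 1))
    expect_equal(degrees(ws_random(40, 4, p, 11))$total_links, 80L)

  cc <- vapply(1:20, function(s) {
    mean(feature_matrix(ws_random(200, 4, 1, s))[, "clustering_coeff"])
  }, 1)
  expect_lt(mean(cc), 0.1)
})

test_that("rewiring series starts at the lattice and conserves edges", {
  nets <- ws_rewiring_series(60, 40, 4, 3, seed = 5)
  expect_length(nets, 60)
  expect_identical(nets[[1]]$adjacency, ring_lattice(40, 4)$adjacency)
  for (t in c(2, 30, 60))
    expect_equal(degrees(nets[[t]])$total_links, 80L)
  # same seed, same series
  nets2 <- ws_rewiring_series(60, 40, 4, 3, seed = 5)
  expect_identical(nets, nets2)
  expect_error(ws_rewiring_series(1000, 40, 4, 3, seed = 1), "shorter")
  # clustering decays across rounds in expectation
  cc_round <- function(nets, idx)
    mean(vapply(nets[idx], function(nt)
      mean(feature_matrix(nt)[, "clustering_coeff"]), 1))
  drops <- vapply(1:10, function(s) {
    ns <- ws_rewiring_series(30, 40, 4, 3, seed = s)
    cc_round(ns, 1:10) - cc_round(ns, 21:30)
  }, 1)
  expect_gt(mean(drops), 0)
  expect_gt(t.test(drops, alternative = "greater")$statistic, 0)
})

test_that("lattice+ER composites carry a correct planted set", {
  comp <- compose_lattice_plus_er(100, 4, 10, 0.25, 2, seed = 3)
  expect_equal(comp$network$n_nodes, 110L)
  expect_length(comp$planted, 10)
  expect_true(all(comp$planted > 100))
  # the lattice block is untouched
  expect_identical(comp$network$adjacency[1:100, 1:100],
                   ring_lattice(100, 4)$adjacency)
  # bridges make it connected; without them two components remain
  comp0 <- compose_lattice_plus_er(100, 4, 10, 0.25, 0, seed = 3)
  expect_equal(sum(comp0$network$adjacency[1:100, 101:110]), 0L)
  expect_identical(compose_lattice_plus_er(50, 4, 8, 0.25, 2, seed = 9),
                   compose_lattice_plus_er(50, 4, 8, 0.25, 2, seed = 9))
})

test_that("embedded 7-node structure has the canonical wiring", {
  host <- er_random(40, 0.2, 21)
  emb <- embed_regular_structure(host, seed = 4)
  net <- emb$network
  expect_equal(net$n_nodes, 47L)
  # host unchanged on its own node set
  expect_identical(net$adjacency[1:40, 1:40], host$adjacency)
  deg <- degrees(net)$degree
  expect_equal(deg[emb$inner], 6L)
  expect_true(all(deg[emb$outer] == 5L))
  # inside the isolated structure: outer degree 4, inner 6, outer cc >= 0.5
  sub <- net$adjacency[c(emb$outer, emb$inner), c(emb$outer, emb$inner)]
  iso <- bta_network(sub)
  expect_equal(degrees(iso)$degree, c(rep(4L, 6), 6L))
  fiso <- feature_matrix(iso)
  expect_true(all(fiso[1:6, "clustering_coeff"] >= 0.5))
  # each outer node touches exactly one distinct host node
  anchors <- which(colSums(net$adjacency[emb$outer, 1:40, drop = FALSE]) > 0)
  expect_length(anchors, 6)
})

test_that("family tree fixture is deterministic, directed and acyclic", {
  ft <- family_tree_fixture()
  expect_true(ft$directed)
  expect_identical(ft, family_tree_fixture())
  # acyclic: some power of A must vanish on the diagonal forever
  A <- ft$adjacency
  B <- A
  for (k in seq_len(ft$n_nodes)) {
    expect_true(all(diag(B) == 0))
    B <- (B %*% A > 0) * 1
  }
  expect_true(all(B == 0))  # nilpotent: a DAG has no long walks
  # a regular periphery exists: some node's neighbours all share one degree
  f <- feature_matrix(ft)
  expect_true(any(f[, "neighbor_degree_cv"] == 0 & degrees(ft)$degree > 0))
})

test_that("generators are pure functions of their seed", {
  expect_identical(er_random(30, 0.2, 42), er_random(30, 0.2, 42))
  expect_identical(ba_random(30, 2, 42), ba_random(30, 2, 42))
  expect_identical(ws_random(30, 4, 0.3, 42), ws_random(30, 4, 0.3, 42))
  expect_false(identical(er_random(30, 0.2, 1), er_random(30, 0.2, 2)))
  # and they do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(er_random(10, 0.5, 7)); after <- runif(1)
  expect_identical(before, after)
})
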