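test_that("vertex-transitive networks produce no singular nodes", {
  fit <- bta(ring_lattice(100, 4))
  expect_equal(fit$singularity$n_singular, 0L)
  expect_equal(fit$fingerprint, c(NO = 1))
  expect_true(fit$projection$degenerate)
  expect_true(all(fit$node_labels == "NO"))
})

test_that("planted ER components are recovered from lattice composites", {
  # all planted nodes flagged; extra flags confined to the nodes whose
  # neighbourhood the bridge edges genuinely perturb
  for (s in 1:20) {
    comp <- compose_lattice_plus_er(100, 4, 15, 0.25, 2, seed = 100 + s)
    fit <- bta(comp$network)
    sing <- fit$singularity$singular_indices
    expect_gt(length(sing), 0)
    expect_true(all(comp$planted %in% sing))
    A <- comp$network$adjacency
    bridge_ends <- which(rowSums(A[1:100, comp$planted, drop = FALSE]) > 0)
    perturbed <- unique(c(bridge_ends,
                          unlist(lapply(bridge_ends,
                                        function(i) which(A[i, ] == 1L)))))
    expect_true(all(setdiff(sing, comp$planted) %in% perturbed))
  }
})

test_that("the family tree's regular periphery is flagged", {
  fit <- bta(family_tree_fixture())
  sing <- fit$singularity$singular_indices
  expect_gt(length(sing), 0)
  f <- fit$features
  expect_true(any(f[sing, "neighbor_degree_cv"] == 0 &
                    f[sing, "norm_avg_degree"] < mean(f[, "norm_avg_degree"])))
})

test_that("repeated fits are identical (the workflow has no random step)", {
  comp <- compose_lattice_plus_er(60, 4, 10, 0.25, 2, seed = 77)
  fits <- replicate(3, bta(comp$network), simplify = FALSE)
  expect_identical(fits[[2]], fits[[1]])
  expect_identical(fits[[3]], fits[[1]])
})

test_that("the fitted object is internally consistent", {
  comp <- compose_lattice_plus_er(60, 4, 12, 0.25, 2, seed = 13)
  fit <- bta(comp$network)
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 72)
  expect_equal(sum(df$singular), fit$singularity$n_singular)
  # logged N_m equals the distinct non-NO labels
  expect_equal(fit$partition$n_groups >=
                 length(setdiff(unique(df$region), "NO")), TRUE)
  expect_equal(sum(fit$fingerprint), 1, tolerance = 1e-12)
  expect_equal(unname(fit$fingerprint["NO"]),
               mean(df$region == "NO"))
  # singular nodes are exactly the lowest-probability ones
  ns <- fit$singularity$n_singular
  expect_equal(sort(fit$probabilities[df$singular == 1]),
               sort(fit$probabilities)[seq_len(ns)])
  # summary/print run quietly
  expect_output(print(fit), "fingerprint")
  expect_output(print(summary(fit)), "singular nodes")
})

test_that("degenerate and undersized inputs are handled explicitly", {
  expect_error(bta(bta_network(matrix(0L, 2, 2))), "at least 3")
  expect_error(bta(bta_network(matrix(0L, 5, 5))), "no links")
})

test_that("a series of identical networks yields identical fingerprints", {
  comp <- compose_lattice_plus_er(50, 4, 10, 0.3, 2, seed = 5)
  sr <- bta_series(list(comp$network, comp$network, comp$network),
                   join_threshold = 1)
  expect_equal(sr$fingerprints[1, ], sr$fingerprints[2, ])
  expect_equal(sr$fingerprints[1, ], sr$fingerprints[3, ])
  expect_true(all(abs(rowSums(sr$fingerprints) - 1) < 1e-9))
})

test_that("a series of pure ring lattices has an empty catalogue", {
  sr <- bta_series(list(ring_lattice(40, 4), ring_lattice(40, 4)),
                   join_threshold = 1)
  expect_equal(length(sr$catalogue$sizes), 0L)
  expect_equal(colnames(sr$fingerprints), "NO")
  expect_true(all(sr$fingerprints == 1))
  expect_equal(sr$n_singular, c(0L, 0L))
})

test_that("series joining is monotone in the threshold", {
  nets <- ws_rewiring_series(30, 40, 4, 3, seed = 9)
  sizes <- vapply(c(0.25, 0.5, 1, 2), function(th)
    length(bta_series(nets, join_threshold = th)$catalogue$sizes), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("experiment runners return consistent bookkeeping", {
  ex <- experiment_lattice_er(er_sizes = c(5, 10), seeds_per_size = 3, seed = 2)
  expect_equal(nrow(ex$conditions), 6)
  expect_true(all(ex$conditions$detected <= ex$conditions$planted))
  expect_true(ex$miss_rate_pct >= 0 && ex$miss_rate_pct <= 100)
  expect_equal(ex$correct_rate_pct, 100 - ex$miss_rate_pct)

  ex2 <- experiment_embedded(models = "er", densities = c(0.05, 0.2),
                             host_n = 60, seed = 3)
  expect_equal(nrow(ex2$runs), 2)
  expect_true(all(ex2$runs$outer_detected <= 6))
  expect_true(ex2$outer_rate_pct >= 0 && ex2$outer_rate_pct <= 100)
  expect_true(ex2$inner_rate_pct >= 0 && ex2$inner_rate_pct <= 100)
})
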