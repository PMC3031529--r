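test_that("ellipse overlap follows the rescaled unit-distance rule", {
  pts <- matrix(0, 3, 2)
  O <- overlap_matrix(pts, c(1, 1))
  expect_true(all(O == 1L))

  pts <- rbind(c(0, 0), c(0.99, 0))
  expect_equal(overlap_matrix(pts, c(1, 1))[1, 2], 1L)
  pts <- rbind(c(0, 0), c(1.01, 0))
  expect_equal(overlap_matrix(pts, c(1, 1))[1, 2], 0L)
  # rescaling: distance measured in units of the axis SDs
  pts <- rbind(c(0, 0), c(1.8, 0))
  expect_equal(overlap_matrix(pts, c(2, 1))[1, 2], 1L)
  expect_equal(overlap_matrix(pts, c(1, 1))[1, 2], 0L)
  expect_error(overlap_matrix(pts, c(0, 1)), "positive")

  # two well-separated triplets of mutually overlapping ellipses
  tri1 <- rbind(c(0, 0), c(0.5, 0), c(0, 0.5))
  tri2 <- tri1 + 10
  O <- overlap_matrix(rbind(tri1, tri2), c(1, 1))
  expect_equal(O[1:3, 1:3], matrix(1L, 3, 3))
  expect_equal(O[4:6, 4:6], matrix(1L, 3, 3))
  expect_true(all(O[1:3, 4:6] == 0L))
})

test_that("clique matrix equals reachability, including matrix-power form", {
  # chain 1-2, 2-3: all three mutually connected
  O <- diag(1L, 3)
  O[1, 2] <- O[2, 1] <- O[2, 3] <- O[3, 2] <- 1L
  expect_true(all(clique_matrix(O) == 1L))
  expect_identical(clique_matrix(diag(1L, 4)), diag(1L, 4))

  boolean_power_oracle <- function(O) {
    m <- nrow(O)
    P <- diag(1L, m); acc <- matrix(0L, m, m)
    for (k in seq_len(m)) {
      P <- (P %*% O > 0) * 1L
      acc <- ((acc + P) > 0) * 1L
    }
    storage.mode(acc) <- "integer"
    acc
  }
  set.seed(23)
  for (rep in 1:200) {
    m <- sample(2:15, 1)
    O <- matrix(0L, m, m)
    up <- which(upper.tri(O))
    O[up] <- as.integer(runif(length(up)) < 0.2)
    O <- O + t(O); diag(O) <- 1L
    storage.mode(O) <- "integer"
    C <- clique_matrix(O)
    expect_identical(C, oracle_reachability(O))
    expect_identical(C, boolean_power_oracle(O))
  }
})

test_that("motif-groups are the overlap components, found deterministically", {
  tri1 <- rbind(c(0, 0), c(0.5, 0), c(0, 0.5))
  pts <- rbind(tri1, tri1 + 10)
  part <- motif_groups(pts, c(1, 1))
  expect_equal(part$n_groups, 2L)
  expect_equal(part$group_labels, c(1L, 1L, 1L, 2L, 2L, 2L))

  # far-apart points: all singletons
  far <- cbind(seq(0, 40, by = 4), 0)
  part <- motif_groups(far, c(1, 1))
  expect_equal(part$n_groups, nrow(far))

  # empty input: empty partition, not an error
  part0 <- motif_groups(matrix(numeric(0), 0, 2), c(1, 1))
  expect_equal(part0$n_groups, 0L)

  # identical results across repeated runs (no random elements)
  set.seed(31)
  pts <- matrix(rnorm(40), 20, 2)
  runs <- replicate(10, motif_groups(pts, c(1, 1)), simplify = FALSE)
  for (r in runs[-1]) expect_identical(r, runs[[1]])
})

test_that("grouping agrees with a union-find oracle on random instances", {
  set.seed(41)
  for (rep in 1:30) {
    m <- sample(2:25, 1)
    pts <- matrix(rnorm(2 * m, sd = 2), m, 2)
    sds <- c(1.3, 0.7)
    part <- motif_groups(pts, sds)
    Y <- sweep(pts, 2, sds, "/")
    linked <- as.matrix(dist(Y)) <= 1
    uf <- oracle_union_find(linked * 1L)
    # identical partitions: same co-membership relation
    expect_identical(outer(part$group_labels, part$group_labels, "=="),
                     outer(uf, uf, "=="))
    # and the numbering is by smallest member
    expect_equal(part$group_labels, uf)
  }
})

test_that("the k-means variant reproduces clear groupings and stays reproducible", {
  tri1 <- rbind(c(0, 0), c(0.5, 0), c(0, 0.5))
  pts <- rbind(tri1, tri1 + 10)
  km <- motif_groups(pts, c(1, 1), method = "kmeans")
  expect_equal(km$n_groups, 2L)
  expect_equal(km$group_labels, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(km, motif_groups(pts, c(1, 1), method = "kmeans"))
  # fit-level switch
  comp <- compose_lattice_plus_er(60, 4, 10, 0.25, 2, seed = 8)
  fit <- bta(comp$network, bta_control(cluster_method = "kmeans"))
  expect_gt(fit$partition$n_groups, 0)
})

test_that("shrinking the overlap radius never merges groups", {
  set.seed(43)
  pts <- matrix(rnorm(30), 15, 2)
  thresholds <- c(2, 1.5, 1, 0.5, 0.25)
  counts <- vapply(thresholds, function(th)
    motif_groups(pts, c(1, 1), threshold = th)$n_groups, 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("relabelling points relabels groups consistently", {
  set.seed(47)
  pts <- matrix(rnorm(24), 12, 2)
  part <- motif_groups(pts, c(1, 1))
  perm <- sample(12)
  part2 <- motif_groups(pts[perm, ], c(1, 1))
  expect_identical(outer(part2$group_labels, part2$group_labels, "=="),
                   outer(part$group_labels[perm], part$group_labels[perm], "=="))
})
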