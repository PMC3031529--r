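# Independent brute-force oracles, written as plain loops over the adjacency
# matrix so they share no code with the implementation they check.

# all six measures for one node, by exhaustive enumeration
oracle_measures <- function(net, i) {
  A <- net$adjacency
  n <- nrow(A)
  U <- if (net$directed) (A + t(A) > 0) * 1 else A
  deg <- if (net$directed) colSums(A) + rowSums(A) else rowSums(U)
  L <- if (net$directed) sum(A) else sum(U) / 2
  nb <- c()
  for (j in seq_len(n)) if (U[i, j] == 1) nb <- c(nb, j)

  navd <- if (length(nb)) mean(deg[nb]) / L else 0
  cv <- 0
  if (length(nb) >= 2 && mean(deg[nb]) > 0) {
    m <- mean(deg[nb])
    cv <- sqrt(mean((deg[nb] - m)^2)) / m
  }
  cc <- 0
  if (length(nb) >= 2) {
    e <- 0
    for (a in nb) for (b in nb) if (a < b && U[a, b] == 1) e <- e + 1
    cc <- e / choose(length(nb), 2)
  }
  # locality: every edge with at least one endpoint in N(i), not touching i
  loc <- 0
  if (length(nb)) {
    tot <- 0; shared <- 0
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a >= b || U[a, b] != 1) next
      if (a == i || b == i) next
      if (!(a %in% nb) && !(b %in% nb)) next
      tot <- tot + 1
      if (a %in% nb && b %in% nb) { shared <- shared + 1; next }
      w <- if (a %in% nb) b else a
      hits <- 0
      for (v in nb) if (U[v, w] == 1) hits <- hits + 1
      if (hits >= 2) shared <- shared + 1
    }
    if (tot > 0) loc <- shared / tot
  }
  # hier_cc2 on exact-distance-2 ring (breadth-first distances)
  distv <- rep(Inf, n); distv[i] <- 0; frontier <- i
  while (length(frontier)) {
    nxt <- c()
    for (v in frontier) for (j in seq_len(n))
      if (U[v, j] == 1 && distv[j] == Inf) { distv[j] <- distv[v] + 1; nxt <- c(nxt, j) }
    frontier <- nxt
  }
  r2 <- which(distv == 2)
  h2 <- 0
  if (length(r2) >= 2) {
    e <- 0
    for (a in r2) for (b in r2) if (a < b && U[a, b] == 1) e <- e + 1
    h2 <- e / choose(length(r2), 2)
  }
  c(norm_avg_degree = navd, neighbor_degree_cv = cv, clustering_coeff = cc,
    locality_index = loc, hier_cc2 = h2, norm_degree = deg[i] / L)
}

# reachability by breadth-first search on a binary symmetric matrix
oracle_reachability <- function(O) {
  m <- nrow(O)
  C <- diag(1L, m)
  for (s in seq_len(m)) {
    seen <- rep(FALSE, m); seen[s] <- TRUE; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (j in seq_len(m)) if (O[v, j] != 0 && !seen[j]) {
        seen[j] <- TRUE; queue <- c(queue, j)
      }
    }
    C[s, seen] <- 1L
  }
  C
}

# union-find partition of points under a pairwise predicate
oracle_union_find <- function(linked) {
  m <- nrow(linked)
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(m)) for (b in seq_len(m))
    if (linked[a, b] != 0) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) { parent[ra] <- min(ra, rb); parent[rb] <- min(ra, rb) }
    }
  roots <- vapply(seq_len(m), find, 1L)
  match(roots, unique(roots))
}

# small random test networks (undirected / directed), seeded
random_test_net <- function(n, density, seed, directed = FALSE) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  if (directed) {
    A[] <- as.integer(matrix(runif(n * n), n, n) < density)
    diag(A) <- 0L
  } else {
    up <- which(upper.tri(A))
    A[up] <- as.integer(runif(length(up)) < density)
    A <- A + t(A)
    storage.mode(A) <- "integer"
  }
  bta_network(A, directed = directed)
}

# ensure a network has at least one link (add one if not)
ensure_link <- function(net) {
  if (sum(net$adjacency) > 0) return(net)
  A <- net$adjacency
  A[1, 2] <- A[2, 1] <- 1L
  bta_network(A, directed = net$directed, labels = net$labels)
}
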