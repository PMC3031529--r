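#' Ring lattice
#'
#' Regular ring of \code{n} nodes in which every node is linked to its
#' \code{k} nearest neighbours (\code{k/2} on either side).  A vertex-
#' transitive graph: every node has degree \code{k} and, for \code{k = 4},
#' local clustering coefficient 1/2.
#'
#' @param n number of nodes, \code{n > k}.
#' @param k even number of neighbours per node, \code{k >= 2}.
#' @return A \code{\link{bta_network}}.
#' @export
ring_lattice <- function(n, k) {
  if (k %% 2L != 0L || k < 2L) stop("k must be even and >= 2", call. = FALSE)
  if (n <= k) stop("need n > k", call. = FALSE)
  A <- matrix(0L, n, n)
  for (d in seq_len(k %/% 2L)) {
    i <- seq_len(n)
    j <- ((i - 1L + d) %% n) + 1L
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  bta_network(A, directed = FALSE)
}

#' Erdos-Renyi random graph
#'
#' Each of the \code{choose(n, 2)} node pairs is linked independently with
#' probability \code{density}.
#'
#' @param n number of nodes.
#' @param density link probability in \code{[0, 1]}.
#' @param seed integer RNG seed; the generator is a pure function of its
#'   arguments.
#' @return A \code{\link{bta_network}}.
#' @export
er_random <- function(n, density, seed) {
  if (density < 0 || density > 1) stop("density must be in [0, 1]",
                                       call. = FALSE)
  if (n < 1L) stop("need n >= 1", call. = FALSE)
  with_seed(seed, {
    A <- matrix(0L, n, n)
    if (n > 1L) {
      up <- which(upper.tri(A))
      hit <- up[stats::runif(length(up)) < density]
      A[hit] <- 1L
      A <- A + t(A)
      storage.mode(A) <- "integer"
    }
    bta_network(A, directed = FALSE)
  })
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Grown from a clique of \code{m} seed nodes; each subsequent node attaches
#' to \code{m} distinct existing nodes with probability proportional to their
#' current degree (uniform while all degrees are zero, i.e. for \code{m = 1}).
#' The result has exactly \code{m * (n - m) + choose(m, 2)} edges.
#'
#' @param n number of nodes.
#' @param m links added per new node, \code{1 <= m < n}.
#' @param seed integer RNG seed.
#' @return A \code{\link{bta_network}}.
#' @export
ba_random <- function(n, m, seed) {
  if (m < 1L || m >= n) stop("need 1 <= m < n", call. = FALSE)
  with_seed(seed, {
    A <- matrix(0L, n, n)
    if (m > 1L) {
      A[seq_len(m), seq_len(m)] <- 1L
      diag(A) <- 0L
    }
    deg <- rowSums(A)
    for (v in seq.int(m + 1L, n)) {
      existing <- seq_len(v - 1L)
      w <- deg[existing]
      targets <- if (sum(w) == 0)
        sample(existing, m)
      else
        sample(existing, m, prob = w)
      A[v, targets] <- 1L
      A[targets, v] <- 1L
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
    storage.mode(A) <- "integer"
    bta_network(A, directed = FALSE)
  })
}

# Rewire the edge {u, v}: keep `keep`, redraw the far endpoint uniformly
# among nodes that are neither `keep` itself nor already adjacent to it.
# Returns the adjacency unchanged when no admissible partner exists.
rewire_one <- function(A, u, v, keep) {
  drop <- if (keep == u) v else u
  n <- nrow(A)
  candidates <- which(A[keep, ] == 0L)
  candidates <- candidates[candidates != keep]
  if (!length(candidates)) return(A)
  new <- if (length(candidates) == 1L) candidates
         else candidates[sample.int(length(candidates), 1L)]
  A[u, v] <- A[v, u] <- 0L
  A[keep, new] <- A[new, keep] <- 1L
  A
}

#' Watts-Strogatz small-world graph
#'
#' Starts from \code{\link{ring_lattice}(n, k)} and visits every edge once;
#' with probability \code{p_rewire} the edge is rewired: one endpoint (chosen
#' at random) is kept and the other is redrawn uniformly, avoiding self-loops
#' and duplicate edges.  The number of edges, \code{n * k / 2}, is conserved.
#'
#' @param n number of nodes.
#' @param k even lattice degree.
#' @param p_rewire rewiring probability in \code{[0, 1]}.
#' @param seed integer RNG seed.
#' @return A \code{\link{bta_network}}.
#' @export
ws_random <- function(n, k, p_rewire, seed) {
  if (p_rewire < 0 || p_rewire > 1) stop("p_rewire must be in [0, 1]",
                                         call. = FALSE)
  lat <- ring_lattice(n, k)
  with_seed(seed, {
    A <- lat$adjacency
    edges <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
    for (e in seq_len(nrow(edges))) {
      if (stats::runif(1) >= p_rewire) next
      u <- edges[e, 1]; v <- edges[e, 2]
      keep <- if (stats::runif(1) < 0.5) u else v
      A <- rewire_one(A, u, v, keep)
    }
    bta_network(A, directed = FALSE)
  })
}

#' Snapshot series of a ring lattice rewiring into a small world
#'
#' The series starts from the unrewired lattice and perturbs it round-robin:
#' the edge list is traversed in \code{n_rounds} full passes and every
#' visited edge is rewired (probability one, one endpoint kept at random, the
#' other redrawn uniformly avoiding self-loops and duplicates).  Snapshots
#' are taken at \code{n_snapshots} evenly spaced points of this schedule,
#' snapshot 1 being the untouched lattice.  The edge count is constant across
#' the whole series.
#'
#' The defaults reproduce the validation series used throughout the package:
#' 600 snapshots of a 200-node, degree-4 lattice rewired over 3 rounds, i.e.
#' one snapshot every 2 rewiring events.
#'
#' @param n_snapshots number of sampled networks; must divide the schedule
#'   length \code{n_rounds * n_nodes * lattice_k / 2}.
#' @param n_nodes,lattice_k lattice size and (even) degree.
#' @param n_rounds full rewiring passes over the edge list.
#' @param seed integer RNG seed.
#' @return A list of \code{n_snapshots} \code{\link{bta_network}} objects.
#' @export
ws_rewiring_series <- function(n_snapshots = 600, n_nodes = 200,
                               lattice_k = 4, n_rounds = 3, seed = 1) {
  n_edges <- n_nodes * lattice_k / 2
  total <- n_rounds * n_edges
  if (n_snapshots > total)
    stop("rewiring schedule (", total, " events) shorter than n_snapshots",
         call. = FALSE)
  if (total %% n_snapshots != 0)
    stop("n_snapshots must divide ", total, " for even spacing",
         call. = FALSE)
  step <- total %/% n_snapshots
  lat <- ring_lattice(n_nodes, lattice_k)
  with_seed(seed, {
    A <- lat$adjacency
    out <- vector("list", n_snapshots)
    out[[1]] <- bta_network(A, directed = FALSE)
    done <- 0L
    snap <- 1L
    for (round in seq_len(n_rounds)) {
      edges <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
      ord <- order(edges[, 1], edges[, 2])
      edges <- edges[ord, , drop = FALSE]
      for (e in seq_len(nrow(edges))) {
        u <- edges[e, 1]; v <- edges[e, 2]
        keep <- if (stats::runif(1) < 0.5) u else v
        A <- rewire_one(A, u, v, keep)
        done <- done + 1L
        if (done %% step == 0L && snap < n_snapshots) {
          snap <- snap + 1L
          out[[snap]] <- bta_network(A, directed = FALSE)
        }
      }
    }
    out
  })
}

#' Ring lattice composed with a planted Erdos-Renyi component
#'
#' Benchmark network with known outliers: the disjoint union of a regular
#' ring lattice and a smaller ER component, connected by \code{n_bridges}
#' random lattice-to-ER edges.  The ER-component node indices are returned as
#' the planted outlier set.
#'
#' @param lattice_n,lattice_k lattice size and (even) degree.
#' @param er_n,er_density ER component size and link density.
#' @param n_bridges number of random connecting edges.
#' @param seed integer RNG seed.
#' @return A list with elements \code{network} and \code{planted} (indices of
#'   the ER-component nodes).
#' @export
compose_lattice_plus_er <- function(lattice_n, lattice_k, er_n, er_density,
                                    n_bridges = 2, seed = 1) {
  lat <- ring_lattice(lattice_n, lattice_k)
  with_seed(seed, {
    er_seed <- sample.int(.Machine$integer.max, 1L)
    er <- er_random(er_n, er_density, er_seed)
    n <- lattice_n + er_n
    A <- matrix(0L, n, n)
    A[seq_len(lattice_n), seq_len(lattice_n)] <- lat$adjacency
    er_idx <- seq.int(lattice_n + 1L, n)
    A[er_idx, er_idx] <- er$adjacency
    placed <- 0L
    while (placed < n_bridges) {
      i <- sample.int(lattice_n, 1L)
      j <- lattice_n + sample.int(er_n, 1L)
      if (A[i, j] == 0L) {
        A[i, j] <- A[j, i] <- 1L
        placed <- placed + 1L
      }
    }
    list(network = bta_network(A, directed = FALSE), planted = er_idx)
  })
}

#' Embed a small regular structure into a host network
#'
#' Appends a canonical 7-node regular structure to \code{host}: an inner hub
#' linked to six outer nodes, the outer nodes arranged in a 6-cycle plus its
#' three long diagonals, and each outer node tied by exactly one edge to a
#' distinct random host node.  Within the structure the outer nodes have
#' degree 4 and are highly clustered on levels one and two, while their
#' single host attachment makes their neighbours' degrees variable -- the
#' feature combination the detector is meant to flag.
#'
#' @param host a \code{\link{bta_network}} with at least 20 nodes.
#' @param seed integer RNG seed (chooses the host attachment points).
#' @return A list with elements \code{network}, \code{outer} (six indices)
#'   and \code{inner} (one index).
#' @export
embed_regular_structure <- function(host, seed = 1) {
  stopifnot(inherits(host, "bta_network"))
  hn <- host$n_nodes
  if (hn < 20L) stop("host must have at least 20 nodes", call. = FALSE)
  with_seed(seed, {
    n <- hn + 7L
    A <- matrix(0L, n, n)
    A[seq_len(hn), seq_len(hn)] <- undirected_structure(host)
    outer <- seq.int(hn + 1L, hn + 6L)
    inner <- hn + 7L
    cyc <- cbind(outer, outer[c(2:6, 1)])
    diag3 <- cbind(outer[1:3], outer[4:6])
    hub <- cbind(rep(inner, 6L), outer)
    anchors <- sample.int(hn, 6L)
    ties <- cbind(outer, anchors)
    for (ed in list(cyc, diag3, hub, ties)) {
      A[ed] <- 1L
      A[ed[, c(2, 1), drop = FALSE]] <- 1L
    }
    list(network = bta_network(A, directed = FALSE),
         outer = outer, inner = inner)
  })
}

#' Synthetic family-tree network
#'
#' A fixed, hand-coded directed network of 28 people across several
#' generations
#' with links pointing from parents to their offspring.  It is a synthetic
#' stand-in for a genealogy: several long ancestor chains form a sparse,
#' perfectly regular periphery (nodes whose neighbours all have the same,
#' low degree), which is the qualitative property the detector should pick
#' up.  Deterministic and acyclic.
#'
#' @return A directed \code{\link{bta_network}}.
#' @export
family_tree_fixture <- function() {
  edges <- c(
    # chain of paternal great-great ancestors feeding into grandpa1
    "anc1", "anc2",  "anc2", "anc3",  "anc3", "anc4",  "anc4", "grandpa1",
    # a second ancestor chain feeding into grandma1
    "anc5", "anc6",  "anc6", "anc7",  "anc7", "grandma1",
    # a third chain on the maternal side
    "anc8", "anc9",  "anc9", "grandpa2",
    # grandparents -> parents and their siblings
    "grandpa1", "father",  "grandma1", "father",
    "grandpa1", "uncle1",  "grandma1", "uncle1",
    "grandpa2", "mother",  "grandma2", "mother",
    "grandpa2", "aunt1",   "grandma2", "aunt1",
    # parents -> children
    "father", "child1",  "mother", "child1",
    "father", "child2",  "mother", "child2",
    "father", "child3",  "mother", "child3",
    # uncle's family
    "uncle1", "cousin1", "auntinlaw", "cousin1",
    "uncle1", "cousin2", "auntinlaw", "cousin2",
    # aunt's family
    "aunt1", "cousin3", "uncleinlaw", "cousin3",
    # grandchildren keep a peripheral chain going
    "child1", "gchild1", "spouse1", "gchild1",
    "gchild1", "ggchild1")
  m <- matrix(edges, ncol = 2, byrow = TRUE)
  labels <- unique(as.vector(t(m)))
  n <- length(labels)
  A <- matrix(0L, n, n)
  A[cbind(match(m[, 1], labels), match(m[, 2], labels))] <- 1L
  bta_network(A, directed = TRUE, labels = labels)
}
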