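# The six local node measures.
#
# Conventions shared by all of them:
#  * the neighbour set of a node is its undirected neighbourhood (for
#    directed networks: union of predecessors and successors);
#  * degree-based quantities use the directed degree convention
#    (in-degree + out-degree for directed networks);
#  * empty neighbourhoods / distance-2 rings yield 0, never NaN, so feature
#    vectors are always finite.

measure_names <- c("norm_avg_degree", "neighbor_degree_cv",
                   "clustering_coeff", "locality_index",
                   "hier_cc2", "norm_degree")

#' Per-node feature matrix of the six local measures
#'
#' Computes, for every node, the six local measures used to characterise
#' nodes before outlier detection, in this fixed column order:
#' \enumerate{
#'   \item \code{norm_avg_degree}: mean degree of the node's neighbours,
#'     normalised (by default by the total number of links);
#'   \item \code{neighbor_degree_cv}: coefficient of variation (population
#'     SD / mean) of the neighbours' degrees;
#'   \item \code{clustering_coeff}: fraction of realised links among the
#'     node's neighbours;
#'   \item \code{locality_index}: fraction of the neighbours' links that run
#'     to a shared target, i.e. to a node hit by at least two members of the
#'     closed neighbourhood (based on the matching index);
#'   \item \code{hier_cc2}: hierarchical clustering coefficient of level two
#'     -- link density among the nodes at shortest-path distance exactly 2;
#'   \item \code{norm_degree}: degree divided by the total number of links.
#' }
#'
#' @param net a \code{\link{bta_network}} with at least one link.
#' @param avg_degree_norm denominator for the normalised average neighbour
#'   degree: \code{"links"} (total link count, the default, mirroring the
#'   degree normalisation) or \code{"maxdeg"} (maximum degree).
#' @return A numeric \code{n_nodes x 6} matrix with the measure names as
#'   column names and node labels as row names.
#' @examples
#' feature_matrix(ring_lattice(10, 4))[1, ]
#' @export
feature_matrix <- function(net, avg_degree_norm = c("links", "maxdeg")) {
  stopifnot(inherits(net, "bta_network"))
  avg_degree_norm <- match.arg(avg_degree_norm)
  U <- undirected_structure(net)
  n <- net$n_nodes
  dg <- degrees(net)
  if (dg$total_links == 0L)
    stop("network has no links; normalised degree undefined", call. = FALSE)
  deg <- dg$degree                       # directed convention
  L <- dg$total_links
  avg_denom <- if (avg_degree_norm == "links") L else max(deg)
  U2 <- U %*% U                          # U2[i, w] = common-neighbour counts
  nbrs <- apply(U == 1L, 1L, which, simplify = FALSE)
  out <- matrix(0, n, 6L, dimnames = list(net$labels, measure_names))
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    nn <- length(nb)
    di <- deg[nb]
    if (nn > 0L) {
      mu <- mean(di)
      out[i, 1L] <- mu / avg_denom
      if (nn >= 2L && mu > 0) {
        sd_pop <- sqrt(mean((di - mu)^2))
        out[i, 2L] <- sd_pop / mu
      }
    }
    if (nn >= 2L) {
      e_in <- sum(U[nb, nb]) / 2
      out[i, 3L] <- e_in / choose(nn, 2)
    } else e_in <- 0
    # locality index: edges incident to the neighbourhood (excluding i);
    # an edge to an outside target w counts as shared once per incident
    # link when >= 2 neighbours hit w; neighbour-neighbour edges always do.
    if (nn > 0L) {
      deg_u <- rowSums(U)
      e_total <- sum(deg_u[nb]) - nn - e_in
      if (e_total > 0) {
        s <- U2[i, ]
        outside <- setdiff(which(s >= 2), c(nb, i))
        shared <- e_in + sum(s[outside])
        out[i, 4L] <- shared / e_total
      }
    }
    r2 <- which(U2[i, ] > 0 & U[i, ] == 0L)
    r2 <- r2[r2 != i]
    if (length(r2) >= 2L)
      out[i, 5L] <- (sum(U[r2, r2]) / 2) / choose(length(r2), 2)
    out[i, 6L] <- deg[i] / L
  }
  out
}

#' Single-measure accessors
#'
#' Scalar versions of the six local measures for one node; thin wrappers
#' around \code{\link{feature_matrix}} semantics, handy for spot checks.
#'
#' @param net a \code{\link{bta_network}}.
#' @param i node index (1-based).
#' @return A single numeric value.
#' @name local-measures
NULL

#' @rdname local-measures
#' @export
norm_degree <- function(net, i) feature_matrix(net)[i, "norm_degree"]

#' @rdname local-measures
#' @export
norm_avg_degree <- function(net, i) feature_matrix(net)[i, "norm_avg_degree"]

#' @rdname local-measures
#' @export
neighbor_degree_cv <- function(net, i)
  feature_matrix(net)[i, "neighbor_degree_cv"]

#' @rdname local-measures
#' @export
clustering_coeff <- function(net, i)
  feature_matrix(net)[i, "clustering_coeff"]

#' @rdname local-measures
#' @export
locality_index <- function(net, i) feature_matrix(net)[i, "locality_index"]

#' @rdname local-measures
#' @export
hier_cc2 <- function(net, i) feature_matrix(net)[i, "hier_cc2"]
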