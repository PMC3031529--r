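# Motif regions and fingerprints.
#
# Each motif-group claims the territory around its centroid; groups whose
# centroids are closer than the join threshold (in axis-rescaled
# coordinates, a diagonal-covariance Mahalanobis metric) are merged into one
# region.  Every node of the network is then assigned either a region letter
# or "NO" (non-motif), and the relative frequencies over these labels form
# the network's fingerprint.

#' Build motif regions from motif-groups
#'
#' Computes one centroid per group and merges, transitively, all groups whose
#' rescaled centroid distance is at most \code{join_threshold}.  Regions are
#' lettered \code{"A"}, \code{"B"}, ... by descending member count (ties by
#' the smaller first centroid coordinate), so \code{"A"} is always the most
#' populated motif region.
#'
#' @param partition a \code{\link{motif_groups}} result.
#' @param points the singular-node coordinates the partition was built from.
#' @param axis_sd per-axis standard deviations (the region metric).
#' @param join_threshold non-negative merge distance in rescaled units.
#'   Deliberately manual: it is the one workflow parameter left to the user.
#' @return An object of class \code{"bta_regions"}: list with
#'   \code{group_centroids}, \code{region_of_group} (letter per group),
#'   \code{region_centroids}, \code{region_sizes}, \code{axis_sd} and
#'   \code{join_threshold}.
#' @export
build_regions <- function(partition, points, axis_sd, join_threshold = 1) {
  stopifnot(inherits(partition, "bta_partition"))
  if (join_threshold < 0) stop("join_threshold must be >= 0", call. = FALSE)
  points <- as.matrix(points)
  g <- partition$group_labels
  k <- partition$n_groups
  d <- ncol(points)
  if (k == 0L) {
    return(structure(
      list(group_centroids = matrix(numeric(0), 0, d),
           region_of_group = character(0),
           region_centroids = matrix(numeric(0), 0, d),
           region_sizes = integer(0),
           axis_sd = axis_sd, join_threshold = join_threshold),
      class = "bta_regions"))
  }
  cent <- matrix(0, k, d)
  for (gr in seq_len(k))
    cent[gr, ] <- colMeans(points[g == gr, , drop = FALSE])
  Y <- sweep(cent, 2L, axis_sd, "/")
  D <- as.matrix(stats::dist(Y))
  merged <- bool_components(D <= join_threshold)
  sizes <- as.integer(tapply(tabulate(g, k), merged, sum))
  rcent <- matrix(0, max(merged), d)
  for (r in seq_len(max(merged))) {
    members <- which(g %in% which(merged == r))
    rcent[r, ] <- colMeans(points[members, , drop = FALSE])
  }
  ord <- order(-sizes, rcent[, 1])
  letters_for <- character(max(merged))
  letters_for[ord] <- region_letters(max(merged))
  structure(
    list(group_centroids = cent,
         region_of_group = letters_for[merged],
         region_centroids = rcent[ord, , drop = FALSE],
         region_sizes = sizes[ord],
         axis_sd = axis_sd, join_threshold = join_threshold),
    class = "bta_regions")
}

#' @export
print.bta_regions <- function(x, ...) {
  k <- length(x$region_sizes)
  cat(sprintf("<bta_regions: %d region%s (%s)>\n", k,
              if (k == 1L) "" else "s",
              paste(region_letters(k), x$region_sizes, sep = ":",
                    collapse = " ")))
  invisible(x)
}

#' Assign every node to a motif region or "NO"
#'
#' Non-singular nodes get the non-motif label \code{"NO"}; each singular
#' node gets the letter of the region with the smallest axis-rescaled
#' Euclidean (diagonal Mahalanobis) distance between the node's coordinates
#' and the region centroid.  Ties are broken toward the node's own group's
#' region, then alphabetically.
#'
#' @param regions a \code{\link{build_regions}} result.
#' @param coords n x d coordinate matrix of all nodes.
#' @param singular_indices indices of the singular nodes, in the order the
#'   partition's points were given.
#' @param partition the matching \code{\link{motif_groups}} result (used
#'   only for tie-breaking); optional.
#' @return Character vector of per-node labels.
#' @export
assign_nodes <- function(regions, coords, singular_indices,
                         partition = NULL) {
  stopifnot(inherits(regions, "bta_regions"))
  coords <- as.matrix(coords)
  labels <- rep("NO", nrow(coords))
  m <- length(singular_indices)
  if (m == 0L || length(regions$region_sizes) == 0L) return(labels)
  letters_all <- region_letters(length(regions$region_sizes))
  Y <- sweep(coords[singular_indices, , drop = FALSE], 2L,
             regions$axis_sd, "/")
  RC <- sweep(regions$region_centroids, 2L, regions$axis_sd, "/")
  own <- if (!is.null(partition))
    regions$region_of_group[partition$group_labels] else NULL
  for (s in seq_len(m)) {
    dists <- sqrt(colSums((t(RC) - Y[s, ])^2))
    best <- dists <= min(dists) + 1e-12
    pick <- letters_all[best]
    if (!is.null(own) && own[s] %in% pick) labels[singular_indices[s]] <- own[s]
    else labels[singular_indices[s]] <- sort(pick)[1]
  }
  labels
}

#' Fingerprint: relative label frequencies
#'
#' The fingerprint of a network is the vector of relative frequencies of its
#' nodes over the motif regions plus the non-motif region \code{"NO"}.
#'
#' @param x a character vector of per-node region labels, or a fitted
#'   \code{\link{bta}} object.
#' @param ... unused.
#' @return Named numeric vector summing to one, regions in alphabetical
#'   order with \code{"NO"} last.
#' @export
fingerprint <- function(x, ...) UseMethod("fingerprint")

#' @export
fingerprint.character <- function(x, ...) {
  stopifnot(length(x) >= 1L)
  tab <- table(x) / length(x)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  regs <- sort(setdiff(names(out), "NO"))
  out[c(regs, intersect("NO", names(out)))]
}

#' @export
fingerprint.bta <- function(x, ...) x$fingerprint
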