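#' Standardise a feature matrix
#'
#' Centres every column at zero and scales it to unit population variance so
#' measures on different scales become comparable before projection.  Columns
#' with zero variance are left at zero and flagged via the
#' \code{"zero_variance"} attribute.
#'
#' @param features numeric matrix (nodes in rows).
#' @return The standardised matrix with a logical \code{"zero_variance"}
#'   attribute, one entry per column.
#' @export
standardize <- function(features) {
  stopifnot(is.matrix(features), nrow(features) >= 2L)
  mu <- colMeans(features)
  ctr <- sweep(features, 2L, mu)
  sd_pop <- sqrt(colMeans(ctr^2))
  zero <- sd_pop < 1e-12
  scl <- ifelse(zero, 1, sd_pop)
  out <- sweep(ctr, 2L, scl, "/")
  out[, zero] <- 0
  attr(out, "zero_variance") <- zero
  out
}

#' Project standardised features to the principal-component plane
#'
#' Principal component analysis of the standardised feature matrix.  The
#' number of retained components is the smallest \code{d} whose cumulative
#' explained variance reaches \code{min_variance}, clipped to
#' \code{[2, d_max]}; if even \code{d_max} components fall short, the
#' \code{variance_warning} flag is set.  Eigenvector signs are fixed
#' deterministically (the largest-magnitude loading of each component is
#' made positive) so repeated runs are bit-identical.
#'
#' A cloud whose points all coincide (e.g. a vertex-transitive network where
#' every node has the same feature vector) is returned with the
#' \code{degenerate} flag set and all-zero coordinates; downstream steps then
#' report zero singular nodes.
#'
#' @param standardized matrix from \code{\link{standardize}}.
#' @param min_variance required explained-variance fraction (default 0.8).
#' @param d_max maximum number of components.
#' @return An object of class \code{"bta_projection"}: list with
#'   \code{coords} (scores, one row per node), \code{axis_sd} (SD of the
#'   scores along each retained axis), \code{explained_variance},
#'   \code{loadings}, \code{d}, \code{degenerate} and
#'   \code{variance_warning}.
#' @export
pca_project <- function(standardized, min_variance = 0.8, d_max = 6) {
  stopifnot(is.matrix(standardized), nrow(standardized) >= 3L)
  n <- nrow(standardized); p <- ncol(standardized)
  if (max(abs(standardized)) < 1e-12) {
    d <- min(2L, p)
    return(structure(
      list(coords = matrix(0, n, d), axis_sd = rep(0, d),
           explained_variance = 1, loadings = matrix(0, p, d),
           d = d, degenerate = TRUE, variance_warning = FALSE),
      class = "bta_projection"))
  }
  pc <- stats::prcomp(standardized, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(ev)
  d <- which(cum >= min_variance - 1e-12)[1]
  if (is.na(d)) d <- length(ev)
  d <- max(2L, d)
  d <- min(d, d_max, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  # deterministic sign convention
  for (a in seq_len(d)) {
    j <- which.max(abs(rot[, a]))
    if (rot[j, a] < 0) rot[, a] <- -rot[, a]
  }
  coords <- sweep(standardized, 2L, pc$center) %*% rot
  structure(
    list(coords = coords,
         axis_sd = unname(apply(coords, 2L, stats::sd)),
         explained_variance = cum[d],
         loadings = rot, d = d,
         degenerate = FALSE,
         variance_warning = cum[d] < min_variance - 1e-12),
    class = "bta_projection")
}

#' @export
print.bta_projection <- function(x, ...) {
  if (x$degenerate)
    cat("<bta_projection: degenerate (all points coincide)>\n")
  else
    cat(sprintf(
      "<bta_projection: %d nodes, d = %d, explained variance %.1f%%%s>\n",
      nrow(x$coords), x$d, 100 * x$explained_variance,
      if (x$variance_warning) " [below target]" else ""))
  invisible(x)
}
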