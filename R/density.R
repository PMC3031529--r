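#' Parzen-window density over the projected cloud
#'
#' Kernel density estimate at every node's position: the average over all
#' nodes (including the node itself) of an axis-aligned ("un-tilted")
#' Gaussian kernel whose per-axis standard deviation is
#' \code{bandwidth_scale * axis_sd[a]}.  Only the axis SDs' ratios are fixed
#' by the cloud shape; the overall scale defaults to \code{n^(-1/6)}
#' (a Scott-type rate for two dimensions), so dense clouds get sharper
#' kernels.
#'
#' @param cloud a \code{\link{pca_project}} result, or a coordinate matrix
#'   (then \code{axis_sd} must be given).
#' @param bandwidth_scale positive multiplier for the per-axis kernel SD;
#'   \code{NULL} for the \code{n^(-1/6)} default.
#' @param axis_sd per-axis standard deviations when \code{cloud} is a bare
#'   matrix.
#' @return Numeric vector of per-node density values (all strictly
#'   positive).
#' @export
parzen_pdf <- function(cloud, bandwidth_scale = NULL, axis_sd = NULL) {
  if (inherits(cloud, "bta_projection")) {
    if (cloud$degenerate)
      stop("degenerate cloud: all points coincide", call. = FALSE)
    coords <- cloud$coords
    axis_sd <- axis_sd %||% cloud$axis_sd
  } else coords <- as.matrix(cloud)
  if (is.null(axis_sd)) stop("axis_sd required", call. = FALSE)
  n <- nrow(coords)
  bandwidth_scale <- bandwidth_scale %||% n^(-1 / 6)
  stopifnot(bandwidth_scale > 0)
  h <- bandwidth_scale * axis_sd
  if (any(h <= 0))
    stop("degenerate axis: zero standard deviation", call. = FALSE)
  dens <- matrix(1, n, n)
  for (a in seq_along(h)) {
    diff <- outer(coords[, a], coords[, a], "-")
    dens <- dens * stats::dnorm(diff, sd = h[a])
  }
  rowMeans(dens)
}

#' Automatic selection of the singular nodes
#'
#' Classifies nodes as singular (outliers) or regular from their estimated
#' probabilities, without a fixed cut-off.  Nodes whose probability lies
#' below the mean minus one standard deviation of all probabilities are
#' candidates; the borderline is then placed at the steepest increase in the
#' sorted probabilities among those candidates, i.e. the number of singular
#' nodes is the candidate position with the largest gap to its successor
#' (smallest position on ties).  If no candidate exists, or the lowest
#' probability undershoots the threshold only minimally (by less than
#' \code{epsilon_rel * sigma}), no node is singular.
#'
#' @param probabilities numeric vector of per-node densities (length >= 3).
#' @param epsilon_rel relative tolerance of the "minimal undershoot" rule.
#' @return An object of class \code{"bta_singularity"}: list with
#'   \code{probabilities}, \code{mu}, \code{sigma}, \code{n_singular} and
#'   \code{singular_indices} (the \code{n_singular} lowest-probability
#'   nodes, ties broken by node index).
#' @export
select_singular <- function(probabilities, epsilon_rel = 0.01) {
  p <- unname(as.numeric(probabilities))
  n <- length(p)
  if (n < 3L) stop("need at least 3 probabilities", call. = FALSE)
  mu <- mean(p)
  sigma <- stats::sd(p)
  ord <- order(p, seq_len(n))
  ps <- p[ord]
  cand <- which(ps < mu - sigma)
  n_s <- 0L
  if (length(cand) && sigma > 0 &&
      (mu - sigma - ps[1]) >= epsilon_rel * sigma) {
    gaps <- ps[cand + 1L] - ps[cand]
    n_s <- unname(cand[which.max(gaps)])
  }
  structure(
    list(probabilities = p, mu = mu, sigma = sigma,
         n_singular = n_s,
         singular_indices = if (n_s > 0L) sort(ord[seq_len(n_s)])
                            else integer(0)),
    class = "bta_singularity")
}

#' @export
print.bta_singularity <- function(x, ...) {
  cat(sprintf(
    "<bta_singularity: %d of %d nodes singular (mu = %.3g, sigma = %.3g)>\n",
    x$n_singular, length(x$probabilities), x$mu, x$sigma))
  invisible(x)
}
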