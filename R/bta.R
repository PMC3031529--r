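#' Control parameters for the BtA workflow
#'
#' Collects every tunable of the analysis.  All parameters except the join
#' threshold are determined automatically from the data at run time; the
#' values here are the automation's own constants.
#'
#' @param min_variance explained-variance fraction the projection must reach
#'   (components are added until it does); default 0.8.
#' @param max_components upper bound on retained components (default 6).
#' @param bandwidth_scale overall Parzen bandwidth multiplier; \code{NULL}
#'   means the \code{n^(-1/6)} automatic rate.
#' @param epsilon_rel relative tolerance of the minimal-undershoot rule in
#'   \code{\link{select_singular}}.
#' @param overlap_threshold ellipse-overlap distance in rescaled units.
#' @param join_threshold region-merge distance in rescaled units.  The one
#'   deliberately manual parameter of the workflow.
#' @param cluster_method \code{"overlap"} (deterministic ellipse-overlap
#'   grouping, the default) or \code{"kmeans"} (classical k-means with K
#'   taken from the overlap components); see \code{\link{motif_groups}}.
#' @param avg_degree_norm see \code{\link{feature_matrix}}.
#' @param fingerprint_scope \code{"all"} counts all nodes (non-singular ones
#'   as \code{"NO"}); \code{"singular"} restricts the fingerprint to the
#'   singular nodes.
#' @return A list of class \code{"bta_control"}.
#' @export
bta_control <- function(min_variance = 0.8, max_components = 6,
                        bandwidth_scale = NULL, epsilon_rel = 0.01,
                        overlap_threshold = 1, join_threshold = 1,
                        cluster_method = c("overlap", "kmeans"),
                        avg_degree_norm = c("links", "maxdeg"),
                        fingerprint_scope = c("all", "singular")) {
  stopifnot(min_variance > 0, min_variance <= 1, max_components >= 2,
            epsilon_rel >= 0, overlap_threshold > 0, join_threshold >= 0)
  if (!is.null(bandwidth_scale)) stopifnot(bandwidth_scale > 0)
  structure(
    list(min_variance = min_variance, max_components = max_components,
         bandwidth_scale = bandwidth_scale, epsilon_rel = epsilon_rel,
         overlap_threshold = overlap_threshold,
         join_threshold = join_threshold,
         cluster_method = match.arg(cluster_method),
         avg_degree_norm = match.arg(avg_degree_norm),
         fingerprint_scope = match.arg(fingerprint_scope)),
    class = "bta_control")
}

#' Fit the single-node-motif workflow to one network
#'
#' Runs the full analysis: (1) six local measures per node; (2)
#' standardisation and projection to the principal-component plane; (3)
#' axis-scaled Gaussian Parzen density over the projected cloud; (4)
#' automatic selection of the singular nodes; (5) deterministic
#' ellipse-overlap clustering into motif-groups; (6-7) motif regions via
#' nearest rescaled centroid, with close regions joined; (8) the fingerprint
#' of relative region frequencies.  Apart from the join threshold all
#' parameters are determined from the data, so the fit needs no tuning and
#' is fully deterministic.
#'
#' Networks whose nodes all share one feature vector (e.g. a pure ring
#' lattice) produce a degenerate projection; the fit then reports zero
#' singular nodes and the fingerprint \code{c(NO = 1)}.
#'
#' @param net a \code{\link{bta_network}} with at least 3 nodes and 1 link.
#' @param control a \code{\link{bta_control}} list.
#' @return An object of class \code{"bta"} with components
#'   \code{features}, \code{projection}, \code{probabilities},
#'   \code{singularity}, \code{partition}, \code{regions},
#'   \code{node_labels} (per-node region letters or \code{"NO"}),
#'   \code{fingerprint}, \code{network} and \code{control}.
#' @examples
#' set.seed(1)
#' comp <- compose_lattice_plus_er(50, 4, 8, 0.3, 2, seed = 7)
#' fit <- bta(comp$network)
#' fit
#' fingerprint(fit)
#' @export
bta <- function(net, control = bta_control()) {
  stopifnot(inherits(net, "bta_network"), inherits(control, "bta_control"))
  if (net$n_nodes < 3L) stop("need at least 3 nodes", call. = FALSE)
  feats <- feature_matrix(net, control$avg_degree_norm)
  z <- standardize(feats)
  proj <- pca_project(z, control$min_variance, control$max_components)

  empty_fit <- function(probs) {
    part <- motif_groups(matrix(numeric(0), 0, proj$d), rep(1, proj$d))
    regs <- build_regions(part, matrix(numeric(0), 0, proj$d),
                          rep(1, proj$d), control$join_threshold)
    finish_bta(net, control, feats, proj, probs,
               structure(list(probabilities = probs, mu = mean(probs),
                              sigma = stats::sd(probs), n_singular = 0L,
                              singular_indices = integer(0)),
                         class = "bta_singularity"),
               part, regs)
  }

  if (proj$degenerate)
    return(empty_fit(rep(1 / net$n_nodes, net$n_nodes)))

  # drop axes the cloud does not extend into; if none is left the cloud is
  # effectively a single point
  live <- proj$axis_sd > 1e-12 * max(proj$axis_sd)
  coords <- proj$coords[, live, drop = FALSE]
  axis_sd <- proj$axis_sd[live]
  probs <- parzen_pdf(coords, control$bandwidth_scale, axis_sd = axis_sd)
  sel <- select_singular(probs, control$epsilon_rel)
  if (sel$n_singular == 0L) {
    part <- motif_groups(matrix(numeric(0), 0, ncol(coords)), axis_sd)
    regs <- build_regions(part, matrix(numeric(0), 0, ncol(coords)),
                          axis_sd, control$join_threshold)
    return(finish_bta(net, control, feats, proj, probs, sel, part, regs))
  }
  pts <- coords[sel$singular_indices, , drop = FALSE]
  part <- motif_groups(pts, axis_sd, control$overlap_threshold,
                       method = control$cluster_method)
  regs <- build_regions(part, pts, axis_sd, control$join_threshold)
  fit <- finish_bta(net, control, feats, proj, probs, sel, part, regs,
                    coords = coords)
  fit
}

# assemble the classed result object
finish_bta <- function(net, control, feats, proj, probs, sel, part, regs,
                       coords = NULL) {
  n <- net$n_nodes
  if (is.null(coords)) coords <- matrix(0, n, max(1L, length(regs$axis_sd)))
  labels <- assign_nodes(regs, coords, sel$singular_indices, part)
  fp_labels <- if (control$fingerprint_scope == "singular" &&
                   sel$n_singular > 0L)
    labels[sel$singular_indices] else labels
  structure(
    list(features = feats, projection = proj, probabilities = probs,
         singularity = sel, partition = part, regions = regs,
         node_labels = labels, fingerprint = fingerprint(fp_labels),
         network = net, control = control),
    class = "bta")
}

#' @export
print.bta <- function(x, ...) {
  fp <- x$fingerprint
  cat(sprintf(
    "Single-node-motif fit: %d nodes, %d singular, %d motif-group%s\n",
    x$network$n_nodes, x$singularity$n_singular, x$partition$n_groups,
    if (x$partition$n_groups == 1L) "" else "s"))
  cat("fingerprint:",
      paste(sprintf("%s=%.3f", names(fp), fp), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.bta <- function(object, ...) {
  structure(list(fit = object), class = "summary.bta")
}

#' @export
print.summary.bta <- function(x, ...) {
  fit <- x$fit
  print(fit$network)
  if (fit$projection$degenerate) {
    cat("projection: degenerate (all feature vectors identical)\n")
  } else {
    cat(sprintf("projection: d = %d, explained variance %.1f%%\n",
                fit$projection$d,
                100 * fit$projection$explained_variance))
  }
  cat(sprintf("probabilities: mu = %.4g, sigma = %.4g\n",
              fit$singularity$mu, fit$singularity$sigma))
  cat(sprintf("singular nodes: %d\n", fit$singularity$n_singular))
  if (fit$singularity$n_singular > 0L) {
    cat("  ", paste(fit$network$labels[fit$singularity$singular_indices],
                    collapse = ", "), "\n")
    cat(sprintf("motif-groups: %d; regions: %d\n", fit$partition$n_groups,
                length(fit$regions$region_sizes)))
  }
  fp <- fit$fingerprint
  cat("fingerprint:",
      paste(sprintf("%s=%.3f", names(fp), fp), collapse = " "), "\n")
  invisible(x)
}

#' Per-node results table
#'
#' @param x a fitted \code{\link{bta}} object.
#' @param ... unused.
#' @return A data frame with one row per node: label, the six measures, the
#'   density value, the singular flag, the motif-group id (NA for regular
#'   nodes) and the region letter.
#' @export
as.data.frame.bta <- function(x, ...) {
  n <- x$network$n_nodes
  grp <- rep(NA_integer_, n)
  if (x$singularity$n_singular > 0L)
    grp[x$singularity$singular_indices] <- x$partition$group_labels
  data.frame(node = x$network$labels, x$features,
             probability = x$probabilities,
             singular = as.integer(seq_len(n) %in%
                                     x$singularity$singular_indices),
             group = grp, region = x$node_labels,
             row.names = NULL, check.names = FALSE)
}

#' Plot a fitted single-node-motif analysis
#'
#' Scatter of the nodes in the plane of the first two principal components;
#' singular nodes are coloured by motif region, regular nodes are grey, and
#' region letters mark the region centroids.
#'
#' @param x a fitted \code{\link{bta}} object.
#' @param ... passed on to \code{plot}.
#' @export
plot.bta <- function(x, ...) {
  if (x$projection$degenerate) {
    plot.new()
    title(main = "degenerate projection: all nodes identical")
    return(invisible(x))
  }
  co <- x$projection$coords
  lab <- x$node_labels
  regs <- sort(setdiff(unique(lab), "NO"))
  col <- rep("grey60", nrow(co))
  if (length(regs)) {
    pal <- grDevices::hcl.colors(max(3L, length(regs)), "Dark 3")
    for (r in seq_along(regs)) col[lab == regs[r]] <- pal[r]
  }
  graphics::plot(co[, 1], co[, 2], col = col,
                 pch = ifelse(lab == "NO", 1, 19),
                 xlab = "PC1", ylab = "PC2", ...)
  if (length(x$regions$region_sizes) && ncol(x$regions$region_centroids) >= 2)
    graphics::text(x$regions$region_centroids[, 1],
                   x$regions$region_centroids[, 2],
                   region_letters(length(x$regions$region_sizes)),
                   font = 2)
  invisible(x)
}
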