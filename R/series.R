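#' Analyse an ordered series of networks with a shared motif catalogue
#'
#' Fits the single-node-motif workflow to every network of a series (e.g.
#' snapshots of an evolving topology) in one common coordinate system, so
#' that motifs can be matched across networks: the feature rows of all
#' networks are pooled, standardised and projected together, and the pooled
#' per-axis standard deviations serve as the kernel/overlap metric
#' throughout.  Outlier selection and motif-grouping then run per network in
#' that shared plane; finally the motif-group centroids of all networks are
#' joined across the series at \code{join_threshold}, which yields the
#' global motif catalogue, and every network is fingerprinted over it.
#'
#' @param nets list of \code{\link{bta_network}} objects (>= 2), analysed
#'   with one common measure configuration.
#' @param join_threshold region-merge distance in rescaled units; manual by
#'   design.
#' @param control a \code{\link{bta_control}} list.
#' @param axis_sd_mode metric for the per-network kernel/overlap steps:
#'   \code{"per_network"} (default) uses each snapshot's own score SDs in
#'   the shared plane, mirroring the single-network workflow; \code{"pooled"}
#'   uses the SDs of the pooled cloud throughout.  Region joining across
#'   networks always uses the pooled SDs, the one common metric.
#' @return An object of class \code{"bta_series"}: list with
#'   \code{n_singular} and \code{n_groups} (one entry per network),
#'   \code{catalogue} (letters, centroids and total sizes of the global
#'   motif regions), \code{fingerprints} (networks x regions matrix,
#'   \code{"NO"} last), \code{projection} (the pooled one) and
#'   \code{per_network} details.
#' @export
bta_series <- function(nets, join_threshold = 1, control = bta_control(),
                       axis_sd_mode = c("per_network", "pooled")) {
  axis_sd_mode <- match.arg(axis_sd_mode)
  stopifnot(is.list(nets), length(nets) >= 2L)
  lapply(nets, function(x) stopifnot(inherits(x, "bta_network")))
  feats <- lapply(nets, feature_matrix, control$avg_degree_norm)
  sizes <- vapply(feats, nrow, 1L)
  pooled <- do.call(rbind, feats)
  z <- standardize(pooled)
  proj <- pca_project(z, control$min_variance, control$max_components)
  nN <- length(nets)
  offsets <- c(0L, cumsum(sizes))
  if (proj$degenerate) {
    fps <- matrix(1, nN, 1, dimnames = list(NULL, "NO"))
    return(structure(
      list(n_singular = rep(0L, nN), n_groups = rep(0L, nN),
           catalogue = list(letters = character(0),
                            centroids = matrix(numeric(0), 0, proj$d),
                            sizes = integer(0)),
           fingerprints = fps, projection = proj,
           per_network = vector("list", nN),
           join_threshold = join_threshold, control = control),
      class = "bta_series"))
  }
  live <- proj$axis_sd > 1e-12 * max(proj$axis_sd)
  axis_sd <- proj$axis_sd[live]
  coords <- proj$coords[, live, drop = FALSE]

  per <- vector("list", nN)
  n_singular <- integer(nN)
  n_groups <- integer(nN)
  all_centroids <- NULL
  all_sizes <- integer(0)
  owner <- integer(0)              # network index of each pooled group
  for (t in seq_len(nN)) {
    idx <- seq.int(offsets[t] + 1L, offsets[t + 1L])
    co <- coords[idx, , drop = FALSE]
    msd <- if (axis_sd_mode == "pooled") axis_sd
           else apply(co, 2L, stats::sd)
    livet <- msd > 1e-12 * max(msd)
    if (max(msd) == 0) {
      # all of this snapshot's points coincide: nothing is singular
      probs <- rep(1 / nrow(co), nrow(co))
      sel <- structure(list(probabilities = probs, mu = probs[1], sigma = 0,
                            n_singular = 0L, singular_indices = integer(0)),
                       class = "bta_singularity")
    } else {
      probs <- parzen_pdf(co[, livet, drop = FALSE],
                          control$bandwidth_scale, axis_sd = msd[livet])
      sel <- select_singular(probs, control$epsilon_rel)
    }
    n_singular[t] <- sel$n_singular
    if (sel$n_singular > 0L) {
      pts <- co[sel$singular_indices, , drop = FALSE]
      part <- motif_groups(pts[, livet, drop = FALSE], msd[livet],
                           control$overlap_threshold)
      n_groups[t] <- part$n_groups
      cent <- matrix(0, part$n_groups, ncol(co))
      gsz <- integer(part$n_groups)
      for (gr in seq_len(part$n_groups)) {
        mem <- part$group_labels == gr
        cent[gr, ] <- colMeans(pts[mem, , drop = FALSE])
        gsz[gr] <- sum(mem)
      }
      all_centroids <- rbind(all_centroids, cent)
      all_sizes <- c(all_sizes, gsz)
      owner <- c(owner, rep(t, part$n_groups))
      per[[t]] <- list(singularity = sel, partition = part, points = pts,
                       group_centroids = cent)
    } else {
      per[[t]] <- list(singularity = sel, partition = NULL, points = NULL,
                       group_centroids = NULL)
    }
  }

  if (is.null(all_centroids)) {
    catalogue <- list(letters = character(0),
                      centroids = matrix(numeric(0), 0, ncol(coords)),
                      sizes = integer(0))
    fps <- matrix(1, nN, 1, dimnames = list(NULL, "NO"))
  } else {
    Y <- sweep(all_centroids, 2L, axis_sd, "/")
    D <- as.matrix(stats::dist(Y))
    merged <- bool_components(D <= join_threshold)
    k <- max(merged)
    msizes <- as.integer(tapply(all_sizes, merged, sum))
    mcent <- matrix(0, k, ncol(coords))
    for (r in seq_len(k)) {
      w <- all_sizes[merged == r]
      mcent[r, ] <- colSums(all_centroids[merged == r, , drop = FALSE] *
                              w) / sum(w)
    }
    ord <- order(-msizes, mcent[, 1])
    letter_of <- character(k)
    letter_of[ord] <- region_letters(k)
    catalogue <- list(letters = region_letters(k),
                      centroids = mcent[ord, , drop = FALSE],
                      sizes = msizes[ord])
    cols <- c(region_letters(k), "NO")
    fps <- matrix(0, nN, k + 1L, dimnames = list(NULL, cols))
    gidx <- 0L
    for (t in seq_len(nN)) {
      nt <- sizes[t]
      labs <- rep("NO", nt)
      if (n_singular[t] > 0L) {
        part <- per[[t]]$partition
        groups_here <- seq.int(gidx + 1L, gidx + part$n_groups)
        region_of_group <- letter_of[merged[groups_here]]
        labs[per[[t]]$singularity$singular_indices] <-
          region_of_group[part$group_labels]
        per[[t]]$region_of_group <- region_of_group
        gidx <- gidx + part$n_groups
      }
      per[[t]]$node_labels <- labs
      fp <- fingerprint(labs)
      fps[t, names(fp)] <- fp
    }
  }
  structure(
    list(n_singular = n_singular, n_groups = n_groups,
         catalogue = catalogue, fingerprints = fps, projection = proj,
         per_network = per, join_threshold = join_threshold,
         axis_sd_mode = axis_sd_mode, control = control),
    class = "bta_series")
}

#' @export
print.bta_series <- function(x, ...) {
  k <- length(x$catalogue$sizes)
  cat(sprintf(
    "<bta_series: %d networks, %d motif%s in catalogue, N_s range %d..%d>\n",
    length(x$n_singular), k, if (k == 1L) "" else "s",
    min(x$n_singular), max(x$n_singular)))
  invisible(x)
}

#' Plot a series analysis
#'
#' Two panels: the per-snapshot singular-node count and the per-snapshot
#' motif-region frequencies from the shared catalogue.
#'
#' @param x a \code{\link{bta_series}} object.
#' @param ... unused.
#' @export
plot.bta_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$n_singular, type = "l", xlab = "snapshot",
                 ylab = "singular nodes")
  fp <- x$fingerprints
  regs <- setdiff(colnames(fp), "NO")
  if (length(regs)) {
    pal <- grDevices::hcl.colors(max(3L, length(regs)), "Dark 3")
    graphics::matplot(fp[, regs, drop = FALSE], type = "l", lty = 1,
                      col = pal[seq_along(regs)], xlab = "snapshot",
                      ylab = "motif frequency")
    graphics::legend("topleft", legend = regs, col = pal[seq_along(regs)],
                     lty = 1, bty = "n")
  }
  invisible(x)
}
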