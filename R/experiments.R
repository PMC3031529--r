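# Validation experiment runners.  Each builds benchmark networks with known
# planted structure, runs the full workflow with default (automatic)
# parameters and scores the recovered singular nodes against the plant.

#' Planted-outlier recovery: ring lattice plus ER component
#'
#' For every ER-component size and seed, composes a regular ring lattice
#' with a denser random component (see
#' \code{\link{compose_lattice_plus_er}}), fits \code{\link{bta}} and scores
#' the planted ER nodes: a planted node is \emph{missed} if it is not
#' flagged singular, and \emph{classified correctly} if it is.  Aggregate
#' rates over the planted outlier-nodes are reported for the conditions in
#' which the ER component holds less than a quarter of the nodes; beyond
#' that share the plant itself starts to contain regular-looking nodes and
#' the planted/detected counts are expected to diverge, so those conditions
#' are reported but not scored.  A whole-network accuracy (planted and
#' singular, or unplanted and regular, over all nodes) is also returned;
#' note that the nodes incident to the bridge edges -- and their lattice
#' neighbours -- genuinely change their local measures when the components
#' are tied together, so a small set of unplanted nodes is structurally
#' singular by construction and bounds this accuracy away from 100\%.
#'
#' @param er_sizes ER-component sizes to sweep.
#' @param seeds_per_size replicate networks per size.
#' @param lattice_n,lattice_k lattice size and degree.
#' @param er_density ER link density.
#' @param n_bridges connecting edges between the components.
#' @param seed master RNG seed; replicate seeds are derived from it.
#' @param control a \code{\link{bta_control}} list.
#' @return An object of class \code{"bta_experiment"} with a per-condition
#'   data frame (\code{$conditions}) and aggregate percentages over the
#'   scored (ER share < 25\%) conditions: \code{$miss_rate_pct} and
#'   \code{$correct_rate_pct} (both over the planted outlier-nodes) and
#'   \code{$accuracy_pct} (over all nodes).
#' @export
experiment_lattice_er <- function(er_sizes = seq(5, 30, by = 5),
                                  seeds_per_size = 20,
                                  lattice_n = 100, lattice_k = 4,
                                  er_density = 0.25, n_bridges = 2,
                                  seed = 1, control = bta_control()) {
  runs <- expand.grid(er_n = er_sizes, rep = seq_len(seeds_per_size))
  sub_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max, nrow(runs)))
  res <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    er_n <- runs$er_n[r]
    comp <- compose_lattice_plus_er(lattice_n, lattice_k, er_n, er_density,
                                    n_bridges, seed = sub_seeds[r])
    fit <- bta(comp$network, control)
    sing <- fit$singularity$singular_indices
    n <- comp$network$n_nodes
    planted <- comp$planted
    hit <- sum(planted %in% sing)
    false_pos <- sum(!(sing %in% planted))
    res[[r]] <- data.frame(
      er_n = er_n, rep = runs$rep[r], n_nodes = n,
      er_fraction = er_n / n,
      planted = length(planted), detected = hit,
      missed = length(planted) - hit, false_positives = false_pos,
      n_singular = length(sing))
  }
  cond <- do.call(rbind, res)
  scored <- cond[cond$er_fraction < 0.25, , drop = FALSE]
  miss <- 100 * sum(scored$missed) / sum(scored$planted)
  acc <- 100 * (1 - sum(scored$missed + scored$false_positives) /
                  sum(scored$n_nodes))
  structure(
    list(conditions = cond, miss_rate_pct = miss,
         correct_rate_pct = 100 - miss, accuracy_pct = acc,
         scored_fraction_limit = 0.25),
    class = "bta_experiment")
}

#' @export
print.bta_experiment <- function(x, ...) {
  cat(sprintf(
    "<bta_experiment: %d runs (ER share < %d%% scored)>\n",
    nrow(x$conditions), round(100 * x$scored_fraction_limit)))
  cat(sprintf(
    "  planted outlier-nodes: %.2f%% missed, %.2f%% classified correctly\n",
    x$miss_rate_pct, x$correct_rate_pct))
  cat(sprintf("  whole-network accuracy: %.2f%%\n", x$accuracy_pct))
  invisible(x)
}

# host generators for the embedded-structure sweep; m / k are chosen so the
# realised edge density tracks the requested one
embed_host <- function(model, n, density, seed) {
  switch(model,
    er = er_random(n, density, seed),
    ba = {
      target <- density * choose(n, 2)
      m_try <- seq_len(min(n - 1L, max(2L, ceiling(2 * target / n))))
      edges <- m_try * (n - m_try) + choose(m_try, 2)
      m <- m_try[which.min(abs(edges - target))]
      ba_random(n, m, seed)
    },
    ws = {
      k <- max(2L, 2L * round(density * (n - 1) / 2))
      if (k >= n) k <- if ((n - 1L) %% 2L == 0L) n - 1L else n - 2L
      ws_random(n, k, 0.1, seed)
    },
    stop("unknown host model: ", model, call. = FALSE))
}

#' Planted-structure recovery: regular structure embedded in random hosts
#'
#' Sweeps host model (ER, BA, WS) and edge density, embeds the canonical
#' 7-node regular structure into each host
#' (\code{\link{embed_regular_structure}}), fits \code{\link{bta}} and
#' records whether all six outer nodes, and separately the inner hub, are
#' flagged singular.
#'
#' @param models subset of \code{c("er", "ba", "ws")}.
#' @param densities edge densities to sweep.
#' @param host_n host size (the published sweep leaves it open; 100 by
#'   default).
#' @param seed master RNG seed.
#' @param control a \code{\link{bta_control}} list.
#' @return An object of class \code{"bta_experiment_embedded"} with the
#'   per-run data frame (\code{$runs}) and the aggregate percentages
#'   \code{$outer_rate_pct} (all six outer nodes singular) and
#'   \code{$inner_rate_pct} (inner node singular).
#' @export
experiment_embedded <- function(models = c("er", "ba", "ws"),
                                densities = seq(0.01, 0.50, by = 0.05),
                                host_n = 100, seed = 1,
                                control = bta_control()) {
  models <- match.arg(models, c("er", "ba", "ws"), several.ok = TRUE)
  grid <- expand.grid(model = models, density = densities,
                      stringsAsFactors = FALSE)
  sub_seeds <- with_seed(seed,
                         matrix(sample.int(.Machine$integer.max,
                                           2L * nrow(grid)), ncol = 2L))
  res <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    host <- embed_host(grid$model[r], host_n, grid$density[r],
                       sub_seeds[r, 1])
    emb <- embed_regular_structure(host, seed = sub_seeds[r, 2])
    fit <- bta(emb$network, control)
    sing <- fit$singularity$singular_indices
    res[[r]] <- data.frame(
      model = grid$model[r], density = grid$density[r],
      outer_detected = sum(emb$outer %in% sing),
      all_outer = all(emb$outer %in% sing),
      inner = emb$inner %in% sing,
      n_singular = length(sing))
  }
  runs <- do.call(rbind, res)
  structure(
    list(runs = runs,
         outer_rate_pct = 100 * mean(runs$all_outer),
         inner_rate_pct = 100 * mean(runs$inner)),
    class = "bta_experiment_embedded")
}

#' @export
print.bta_experiment_embedded <- function(x, ...) {
  cat(sprintf(
    "<bta_experiment_embedded: %d runs; all-outer %.1f%%, inner %.1f%%>\n",
    nrow(x$runs), x$outer_rate_pct, x$inner_rate_pct))
  invisible(x)
}
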