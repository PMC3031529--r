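#' Construct a network from an adjacency matrix
#'
#' The package's graph container is deliberately small: a binary adjacency
#' matrix \code{A} with \code{A[i, j] = 1} iff a link runs from node \code{i}
#' to node \code{j}, a flag saying whether links are directed, and one label
#' per node.  Self-loops are disallowed and undirected networks must have a
#' symmetric adjacency.
#'
#' @param adjacency square numeric matrix of 0/1 entries.
#' @param directed logical; if \code{FALSE} the matrix must be symmetric.
#' @param labels character vector of unique node labels; defaults to
#'   \code{"n0" ... "n{k-1}"}.
#' @return An object of class \code{"bta_network"}: a list with elements
#'   \code{adjacency} (integer matrix), \code{directed}, \code{labels} and
#'   \code{n_nodes}.
#' @examples
#' net <- bta_network(matrix(c(0, 1, 1, 0), 2), directed = FALSE)
#' degrees(net)
#' @export
bta_network <- function(adjacency, directed = FALSE, labels = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix", call. = FALSE)
  n <- nrow(adjacency)
  dimnames(adjacency) <- NULL
  storage.mode(adjacency) <- "integer"
  if (any(is.na(adjacency)) || any(adjacency != 0L & adjacency != 1L))
    stop("adjacency entries must be 0 or 1", call. = FALSE)
  if (any(diag(adjacency) != 0L))
    stop("self-loops are not allowed (non-zero diagonal)", call. = FALSE)
  if (!directed && !identical(adjacency, t(adjacency)))
    stop("undirected network requires a symmetric adjacency matrix",
         call. = FALSE)
  if (is.null(labels)) labels <- paste0("n", seq_len(n) - 1L)
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stop("labels must be unique and one per node", call. = FALSE)
  structure(
    list(adjacency = adjacency, directed = directed, labels = labels,
         n_nodes = n),
    class = "bta_network")
}

#' @export
print.bta_network <- function(x, ...) {
  d <- degrees(x)
  cat(sprintf("<bta_network: %d nodes, %d %s links>\n",
              x$n_nodes, d$total_links,
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Node degrees and link count
#'
#' Row and column sums of the adjacency matrix give the out- and in-degrees.
#' For undirected networks in-, out- and total degree coincide; for directed
#' ones the degree of a node is the sum of its in- and out-degree.
#'
#' @param net a \code{\link{bta_network}}.
#' @return A list with integer vectors \code{in_degree}, \code{out_degree},
#'   \code{degree} and the scalar \code{total_links}.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "bta_network"))
  A <- net$adjacency
  outd <- as.integer(rowSums(A))
  ind <- as.integer(colSums(A))
  if (net$directed) {
    list(in_degree = ind, out_degree = outd, degree = ind + outd,
         total_links = sum(A))
  } else {
    list(in_degree = ind, out_degree = outd, degree = outd,
         total_links = sum(A) %/% 2L)
  }
}

# Symmetrised 0/1 neighbour structure; the measures treat directed links as
# undirected except where degrees enter explicitly.
undirected_structure <- function(net) {
  A <- net$adjacency
  if (net$directed) {
    U <- (A + t(A) > 0L) * 1L
    storage.mode(U) <- "integer"
    U
  } else A
}

#' Read a network from an edge-list file
#'
#' One edge per line, two whitespace- (or \code{delimiter}-) separated node
#' labels.  Lines starting with \code{#} and blank lines are ignored; a third
#' column (e.g. a weight) is ignored with a warning because the analysis is
#' unweighted.  Repeated edges collapse to one; self-loops are an error.
#'
#' @param path file path.
#' @param directed logical.
#' @param delimiter field separator; default any whitespace.
#' @return A \code{\link{bta_network}} with labels in first-appearance order.
#' @export
read_edgelist <- function(path, directed = FALSE, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  from <- character(0); to <- character(0)
  warned_extra <- FALSE
  for (ln in idx) {
    parts <- if (is.null(delimiter)) strsplit(trimws(lines[ln]), "\\s+")[[1]]
             else strsplit(trimws(lines[ln]), delimiter, fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 2L)
      stop(sprintf("malformed edge on line %d: need two node labels", ln),
           call. = FALSE)
    if (length(parts) > 2L && !warned_extra) {
      warning("extra columns in edge list ignored (unweighted analysis)",
              call. = FALSE)
      warned_extra <- TRUE
    }
    if (parts[1] == parts[2])
      stop(sprintf("self-loop on line %d: '%s'", ln, parts[1]),
           call. = FALSE)
    from <- c(from, parts[1]); to <- c(to, parts[2])
  }
  labels <- unique(c(rbind(from, to)))
  n <- length(labels)
  A <- matrix(0L, n, n)
  i <- match(from, labels); j <- match(to, labels)
  A[cbind(i, j)] <- 1L
  if (!directed) A[cbind(j, i)] <- 1L
  bta_network(A, directed = directed, labels = labels)
}

#' Read a network from a dense adjacency-matrix file
#'
#' @param path delimited text file holding a square 0/1 matrix.
#' @param directed logical; if \code{FALSE} the matrix must be symmetric.
#' @return A \code{\link{bta_network}} with synthetic labels
#'   \code{"n0" ... "n{k-1}"}.
#' @export
read_adjacency <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  A <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(A) != ncol(A))
    stop("adjacency file is not square: ", nrow(A), "x", ncol(A),
         call. = FALSE)
  bta_network(A, directed = directed)
}

#' Write a network as an edge-list file
#'
#' Inverse of \code{\link{read_edgelist}}: undirected edges are written once
#' (smaller index first).
#'
#' @param net a \code{\link{bta_network}}.
#' @param path output file path.
#' @export
write_edgelist <- function(net, path) {
  A <- net$adjacency
  if (net$directed) {
    idx <- which(A == 1L, arr.ind = TRUE)
  } else {
    idx <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
  }
  lines <- paste(net$labels[idx[, 1]], net$labels[idx[, 2]])
  writeLines(lines, path)
  invisible(path)
}
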