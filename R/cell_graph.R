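#' Build the cell graph from nucleus centroids
#'
#' Nodes are nucleus centroids; a directed edge (i, j) exists iff j is
#' among the K nearest neighbours of i (Euclidean distance, excluding i,
#' ties at the K-th neighbour broken by lower node index) AND
#' D(i, j) < d (strict). The undirected adjacency A is the OR-
#' symmetrization of the directed edges, and the propagation matrix is
#' the self-looped symmetric normalization
#' `A_norm = D~^(-1/2) (A + I) D~^(-1/2)`.
#'
#' @param centroids m x 2 matrix of (row, col) positions in pixels.
#' @param node_features optional m x f feature matrix.
#' @param K neighbours per node (default 5).
#' @param d distance threshold in pixels (default 50 at the synthetic
#'   tile scale).
#' @return object of class `cell_graph` with `centroids`,
#'   `node_features`, `directed_edges` (2-column matrix of (i, j)), `A`,
#'   `A_norm`, `K`, `d`.
#' @export
build_graph <- function(centroids, node_features = NULL, K = 5L, d = 50) {
  centroids <- as.matrix(centroids)
  m <- nrow(centroids)
  stopifnot(m >= 1, ncol(centroids) == 2, K >= 1, d > 0)
  edges <- matrix(integer(0), 0, 2)
  if (m > 1) {
    D <- as.matrix(dist(centroids))
    el <- lapply(seq_len(m), function(i) {
      ord <- order(D[i, -i], seq_len(m)[-i])
      nb <- (seq_len(m)[-i])[ord][seq_len(min(K, m - 1L))]
      nb <- nb[D[i, nb] < d]
      if (length(nb)) cbind(i, nb) else NULL
    })
    edges <- do.call(rbind, el)
    if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  }
  A <- matrix(0, m, m)
  if (nrow(edges) > 0) {
    A[edges] <- 1
    A[edges[, 2:1, drop = FALSE]] <- 1
  }
  structure(list(centroids = centroids, node_features = node_features,
                 directed_edges = unname(edges),
                 A = A, A_norm = normalize_adjacency(A),
                 K = as.integer(K), d = d),
            class = "cell_graph")
}

#' Self-looped symmetric normalization of an adjacency matrix
#'
#' Computes `D~^(-1/2) (A + I) D~^(-1/2)` where `D~` is the degree matrix
#' of `A + I`. Row sums of `A + I` are always >= 1, so the operation is
#' defined for any symmetric binary A with zero diagonal.
#'
#' @param A symmetric binary matrix with zero diagonal.
#' @return the normalized propagation matrix.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), all(A == t(A)), all(diag(A) == 0))
  At <- A + diag(nrow(A))
  dh <- 1 / sqrt(rowSums(At))
  At * outer(dh, dh)
}

#' Serialize / read a cell graph as JSON
#'
#' Stores centroids, node features, directed edges, the symmetrized
#' adjacency and the parameters K and d; the normalized adjacency is
#' recomputed on load. Loading validates that A is symmetric with zero
#' diagonal and consistent with the edge list.
#'
#' @param graph a `cell_graph`.
#' @param path JSON file path.
#' @return `read_cell_graph` returns the `cell_graph`.
#' @export
write_cell_graph <- function(graph, path) {
  stopifnot(inherits(graph, "cell_graph"))
  payload <- list(centroids = graph$centroids,
                  node_features = graph$node_features,
                  directed_edges = graph$directed_edges,
                  A = graph$A, K = graph$K, d = graph$d)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_cell_graph
#' @export
read_cell_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- if (length(x$centroids)) nrow(as.matrix(x$centroids)) else 0L
  if (m == 0L) {
    return(structure(list(centroids = matrix(numeric(0), 0, 2),
                          node_features = NULL,
                          directed_edges = matrix(integer(0), 0, 2),
                          A = matrix(0, 0, 0), A_norm = matrix(0, 0, 0),
                          K = as.integer(x$K), d = x$d),
                     class = "cell_graph"))
  }
  A <- matrix(as.numeric(x$A), m, m, byrow = FALSE)
  # jsonlite reads rowmajor-written matrices back as a matrix already
  if (is.matrix(x$A)) A <- x$A
  if (!isTRUE(all.equal(A, t(A))) || any(diag(A) != 0))
    stop("read_cell_graph: adjacency must be symmetric with zero diagonal")
  edges <- matrix(as.integer(as.matrix(x$directed_edges)), ncol = 2)
  if (nrow(edges) > 0 && any(A[edges] != 1))
    stop("read_cell_graph: edge list inconsistent with adjacency")
  structure(list(centroids = as.matrix(x$centroids),
                 node_features = if (length(x$node_features))
                   as.matrix(x$node_features) else NULL,
                 directed_edges = edges,
                 A = A, A_norm = normalize_adjacency(A),
                 K = as.integer(x$K), d = x$d),
            class = "cell_graph")
}

#' Export the symmetrized adjacency as a MatrixMarket sparse matrix
#'
#' @param graph a `cell_graph`.
#' @param path output `.mtx` path.
#' @export
write_adjacency_mtx <- function(graph, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(graph$A, sparse = TRUE),
                              "generalMatrix"), path)
  invisible(path)
}
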