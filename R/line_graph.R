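#' Extract the canonical edge list of a connectome
#'
#' Edges are the strictly-upper-triangular entries of the adjacency matrix
#' with weight at or above the absence threshold, enumerated in row-major
#' upper-triangular order: (1,2), (1,3), ..., (1,N), (2,3), ... This fixed
#' ordering guarantees that edge-level feature vectors align across
#' subjects sharing a parcellation.
#'
#' @param connectome a [node_connectome()].
#' @return An object of class `edge_list`: a data frame with columns `i`,
#'   `j` (1-based node indices, `i < j`) and `w` (weight), with attributes
#'   `n_nodes` and `L` (edge count). On-disk writers convert indices to
#'   0-based.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 0.5; A[2, 3] <- A[3, 2] <- 0.2
#' build_edge_list(node_connectome(A))
#' @export
build_edge_list <- function(connectome) {
  stopifnot_connectome(connectome)
  A <- connectome$adjacency
  n <- connectome$n_nodes
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  # row-major upper-triangular order: sort by i then j
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  el <- data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                   w = A[idx])
  attr(el, "n_nodes") <- n
  attr(el, "L") <- nrow(el)
  class(el) <- c("edge_list", "data.frame")
  el
}

#' Full upper-triangle edge index for cross-subject feature alignment
#'
#' All N(N-1)/2 unordered node pairs in canonical order, regardless of
#' which are present in any given subject (e.g., 7140 pairs for N = 120).
#' Subjects' edge-level values are scattered onto this index with
#' [align_edge_features()].
#'
#' @param n_nodes parcellation size N.
#' @return data frame with columns `i`, `j` and the pair's position `k`.
#' @export
edge_feature_index <- function(n_nodes) {
  stopifnot(n_nodes >= 1)
  ut <- which(upper.tri(diag(n_nodes)), arr.ind = TRUE)
  ord <- order(ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]
  data.frame(i = as.integer(ut[, 1]), j = as.integer(ut[, 2]),
             k = seq_len(nrow(ut)))
}

#' Scatter per-edge values onto the full upper-triangle feature index
#'
#' @param values numeric vector aligned to `edge_list`.
#' @param edge_list an [build_edge_list()] result.
#' @param n_nodes parcellation size (defaults to the edge list's).
#' @param missing value for node pairs with no edge in this subject
#'   (default 0; use `NA` to mark them missing instead).
#' @return numeric vector of length `n_nodes * (n_nodes - 1) / 2`.
#' @export
align_edge_features <- function(values, edge_list, n_nodes = NULL,
                                missing = 0) {
  if (is.null(n_nodes)) n_nodes <- attr(edge_list, "n_nodes")
  if (length(values) != nrow(edge_list)) {
    stop("values length ", length(values), " != edge count ", nrow(edge_list))
  }
  out <- rep(missing, n_nodes * (n_nodes - 1) / 2)
  # position of pair (i, j), i < j, in row-major upper-triangular order
  k <- (edge_list$i - 1) * n_nodes - edge_list$i * (edge_list$i - 1) / 2 +
    (edge_list$j - edge_list$i)
  out[k] <- values
  out
}

#' Build the weighted node-by-edge incidence matrix
#'
#' Each column corresponds to one edge alpha = (i, j, w) and carries
#' sqrt(w) in rows i and j, zero elsewhere. This square-root convention is
#' the one under which the incidence matrix reproduces the adjacency plus
#' degree structure of the graph: C %*% t(C) == A + D, with D the diagonal
#' matrix of weighted nodal strengths.
#'
#' @param edge_list an [build_edge_list()] result.
#' @param n_nodes number of nodes N (defaults to the edge list's).
#' @return N x L numeric matrix C.
#' @examples
#' A <- matrix(c(0, 4, 0, 4, 0, 9, 0, 9, 0), 3, 3)
#' el <- build_edge_list(node_connectome(A))
#' C <- build_incidence(el)
#' C %*% t(C)  # equals A + diag(strength)
#' @export
build_incidence <- function(edge_list, n_nodes = NULL) {
  if (is.null(n_nodes)) n_nodes <- attr(edge_list, "n_nodes")
  L <- nrow(edge_list)
  C <- matrix(0, n_nodes, L)
  if (L == 0) return(C)
  if (any(edge_list$i < 1) || any(edge_list$j > n_nodes)) {
    stop("edge index out of range [1, ", n_nodes, "]")
  }
  sw <- sqrt(edge_list$w)
  C[cbind(edge_list$i, seq_len(L))] <- sw
  C[cbind(edge_list$j, seq_len(L))] <- sw
  C
}

#' Build the edge-centric (line-graph) adjacency matrix
#'
#' Two edges are adjacent when they share exactly one endpoint; the
#' line-graph weight is then sqrt(w_alpha * w_beta), i.e. the off-diagonal
#' part of t(C) %*% C. The diagonal is set to zero so that the result is a
#' proper adjacency matrix for controllability and energy computations.
#'
#' @param incidence N x L incidence matrix from [build_incidence()].
#' @param edge_list the matching [build_edge_list()] result.
#' @param connectome optional originating [node_connectome()], kept as
#'   provenance.
#' @return An object of class `edge_network`: list with `edge_adjacency`
#'   (L x L symmetric, zero diagonal), `edge_weights` (length L), the
#'   `edge_list`, `n_nodes`, and `source` (the connectome or NULL).
#' @export
build_edge_adjacency <- function(incidence, edge_list, connectome = NULL) {
  L <- nrow(edge_list)
  if (ncol(incidence) != L) {
    stop("incidence has ", ncol(incidence), " columns but edge list has ",
         L, " edges")
  }
  AE <- crossprod(incidence)
  diag(AE) <- 0
  structure(list(edge_adjacency = AE,
                 edge_weights = edge_list$w,
                 edge_list = edge_list,
                 n_nodes = nrow(incidence),
                 source = connectome),
            class = "edge_network")
}

#' Convert a connectome to its edge-centric network in one step
#'
#' Convenience wrapper chaining [build_edge_list()], [build_incidence()]
#' and [build_edge_adjacency()].
#'
#' @param connectome a [node_connectome()].
#' @return An `edge_network`.
#' @export
edge_network <- function(connectome) {
  el <- build_edge_list(connectome)
  C <- build_incidence(el, connectome$n_nodes)
  build_edge_adjacency(C, el, connectome)
}

#' @exportS3Method base::print
print.edge_network <- function(x, ...) {
  cat(sprintf("edge_network: %d edges on %d nodes (line graph)\n",
              nrow(x$edge_list), x$n_nodes))
  invisible(x)
}
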