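#' Construct a node-level connectome
#'
#' Wraps a weighted, symmetric, nonnegative adjacency matrix together with
#' node labels, nodal strengths, and the absence threshold below which
#' weights are treated as numerical noise from tractography and zeroed.
#'
#' @param adjacency square numeric matrix of nonnegative weights; must be
#'   symmetric to within `tol` and is symmetrized on construction. The
#'   diagonal is forced to zero.
#' @param node_labels optional character vector of length `nrow(adjacency)`;
#'   defaults to `"n1"..."nN"`.
#' @param absence_threshold weights strictly below this value are set to 0
#'   (default 0.001, the conventional cutoff for spurious streamline
#'   weights).
#' @param tol maximum tolerated asymmetry `max|A - t(A)|` before the input
#'   is rejected.
#' @return An object of class `node_connectome`: a list with elements
#'   `adjacency`, `node_labels`, `strength` (row sums of `adjacency`, the
#'   diagonal of the degree matrix D), `absence_threshold`, and `n_nodes`.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 0.5; A[2, 3] <- A[3, 2] <- 0.2
#' con <- node_connectome(A)
#' con$strength
#' @export
node_connectome <- function(adjacency, node_labels = NULL,
                            absence_threshold = 0.001, tol = 1e-8) {
  adjacency <- as.matrix(adjacency)
  if (!is.numeric(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be a square numeric matrix, got ",
         nrow(adjacency), "x", ncol(adjacency))
  }
  if (anyNA(adjacency)) stop("adjacency contains missing values")
  asym <- max(abs(adjacency - t(adjacency)))
  if (asym > tol) {
    stop("adjacency is asymmetric: max|A - t(A)| = ", format(asym))
  }
  neg <- which(adjacency < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative weight at cell (%d, %d): %g",
                 neg[1, 1], neg[1, 2], adjacency[neg[1, 1], neg[1, 2]]))
  }
  if (absence_threshold < 0) stop("absence_threshold must be nonnegative")
  adjacency <- (adjacency + t(adjacency)) / 2
  diag(adjacency) <- 0
  adjacency[adjacency < absence_threshold] <- 0
  n <- nrow(adjacency)
  if (is.null(node_labels)) {
    node_labels <- if (!is.null(rownames(adjacency))) rownames(adjacency)
                   else paste0("n", seq_len(n))
  }
  if (length(node_labels) != n) {
    stop("node_labels length ", length(node_labels), " != n_nodes ", n)
  }
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(adjacency = adjacency,
                 node_labels = as.character(node_labels),
                 strength = rowSums(adjacency),
                 absence_threshold = absence_threshold,
                 n_nodes = n),
            class = "node_connectome")
}

#' @exportS3Method base::print
print.node_connectome <- function(x, ...) {
  L <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat(sprintf("node_connectome: %d nodes, %d edges, density %.3f\n",
              x$n_nodes, L, 2 * L / (x$n_nodes * (x$n_nodes - 1))))
  cat(sprintf("  absence threshold %g, mean strength %.4g\n",
              x$absence_threshold, mean(x$strength)))
  invisible(x)
}

stopifnot_connectome <- function(x) {
  if (!inherits(x, "node_connectome")) {
    stop("expected a node_connectome; see node_connectome()")
  }
  invisible(x)
}
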