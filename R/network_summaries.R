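#' Assign nodes to canonical networks
#'
#' @param node_to_network character/factor vector, one network label per
#'   node (e.g., the 7 canonical resting-state systems).
#' @return object of class `canonical_partition`: list with
#'   `node_to_network` (character), `networks` (sorted unique labels), `K`,
#'   and `n_pairs` = K(K+1)/2 unordered within/between pairs (28 for
#'   K = 7).
#' @export
canonical_partition <- function(node_to_network) {
  if (anyNA(node_to_network)) {
    stop("unlabeled node(s) at index: ",
         paste(utils::head(which(is.na(node_to_network)), 5), collapse = ", "))
  }
  labels <- as.character(node_to_network)
  networks <- sort(unique(labels))
  K <- length(networks)
  structure(list(node_to_network = labels, networks = networks,
                 K = K, n_pairs = K * (K + 1) / 2),
            class = "canonical_partition")
}

#' Unordered network-pair label of each edge
#'
#' @param partition a [canonical_partition()].
#' @param edge_list an [build_edge_list()] result.
#' @return character vector, one `"X-Y"` label per edge with the two
#'   network names in sorted order (within-network edges get `"X-X"`).
#' @export
edge_pair_labels <- function(partition, edge_list) {
  stopifnot(inherits(partition, "canonical_partition"))
  nets <- partition$node_to_network
  if (max(edge_list$j) > length(nets)) {
    stop("partition covers ", length(nets), " nodes but edges reference node ",
         max(edge_list$j))
  }
  a <- nets[edge_list$i]
  b <- nets[edge_list$j]
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Mean of incident-edge values for every node
#'
#' Maps edge-level values back to nodes: each node receives the mean of
#' the values on its incident edges (the node-mean edge controllability
#' when fed eAC or eMC). Isolated nodes get NA.
#'
#' @param values numeric vector aligned to `edge_list`.
#' @param edge_list an [build_edge_list()] result.
#' @param n_nodes number of nodes (defaults to the edge list's).
#' @return numeric vector of length `n_nodes`.
#' @export
node_mean_edge_values <- function(values, edge_list, n_nodes = NULL) {
  if (is.null(n_nodes)) n_nodes <- attr(edge_list, "n_nodes")
  if (length(values) != nrow(edge_list)) {
    stop("values length ", length(values), " != edge count ", nrow(edge_list))
  }
  sums <- numeric(n_nodes)
  counts <- integer(n_nodes)
  for (col in c("i", "j")) {
    t_s <- tapply(values, edge_list[[col]], sum)
    t_c <- tapply(values, edge_list[[col]], length)
    at <- as.integer(names(t_s))
    sums[at] <- sums[at] + as.numeric(t_s)
    counts[at] <- counts[at] + as.integer(t_c)
  }
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out
}

#' Whole-brain total of an edge-level measure
#'
#' @param values numeric vector of per-edge values (e.g., eAC).
#' @return their sum (0 for an empty network).
#' @export
whole_brain_sum <- function(values) {
  if (length(values) == 0) return(0)
  sum(values)
}

#' Aggregate edge values into a network-by-network table
#'
#' Entry (m, n) collects the values of edges with one endpoint in network
#' m and the other in network n; within-network aggregates sit on the
#' diagonal. With `fun = "sum"` (default) the unordered-pair totals add up
#' exactly to [whole_brain_sum()]; `fun = "mean"` gives size-normalized
#' values for heatmap display.
#'
#' @param values numeric vector aligned to `edge_list`.
#' @param partition a [canonical_partition()].
#' @param edge_list an [build_edge_list()] result.
#' @param fun `"sum"` or `"mean"`.
#' @return list with `matrix` (K x K symmetric, NA where no edges) and
#'   `table` (long format: network_a, network_b, value, n_edges).
#' @export
aggregate_by_pair <- function(values, partition, edge_list,
                              fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  labels <- edge_pair_labels(partition, edge_list)
  nets <- partition$networks
  K <- partition$K
  mat <- matrix(NA_real_, K, K, dimnames = list(nets, nets))
  a <- partition$node_to_network[edge_list$i]
  b <- partition$node_to_network[edge_list$j]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  agg <- if (fun == "sum") tapply(values, paste(lo, hi, sep = "\r"), sum)
         else tapply(values, paste(lo, hi, sep = "\r"), mean)
  cnt <- tapply(values, paste(lo, hi, sep = "\r"), length)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  tab <- data.frame(network_a = vapply(parts, `[`, "", 1),
                    network_b = vapply(parts, `[`, "", 2),
                    value = as.numeric(agg),
                    n_edges = as.integer(cnt))
  for (r in seq_len(nrow(tab))) {
    mat[tab$network_a[r], tab$network_b[r]] <- tab$value[r]
    mat[tab$network_b[r], tab$network_a[r]] <- tab$value[r]
  }
  list(matrix = mat, table = tab)
}
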