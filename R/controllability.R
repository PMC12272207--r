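#' Rescale a symmetric matrix so the discrete dynamics are stable
#'
#' Divides the matrix by 1 + lambda_max (largest eigenvalue), the standard
#' normalization under which the discrete linear system x(t+1) = A x(t) is
#' stable and the controllability Gramian series converges.
#'
#' @param raw_matrix symmetric numeric matrix.
#' @param tol asymmetry tolerance.
#' @return list with `system_matrix` (rescaled) and `stabilization_factor`
#'   (the divisor, 1 + lambda_max).
#' @export
stabilize <- function(raw_matrix, tol = 1e-8) {
  raw_matrix <- as.matrix(raw_matrix)
  if (nrow(raw_matrix) != ncol(raw_matrix) ||
      max(abs(raw_matrix - t(raw_matrix))) > tol) {
    stop("stabilize() requires a square symmetric matrix")
  }
  lam_max <- if (nrow(raw_matrix) == 0) 0 else
    max(eigen(raw_matrix, symmetric = TRUE, only.values = TRUE)$values)
  factor <- 1 + lam_max
  list(system_matrix = raw_matrix / factor, stabilization_factor = factor)
}

spectral_radius <- function(A) {
  if (nrow(A) == 0) return(0)
  max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
}

#' Average controllability of single control elements
#'
#' For the discrete system x(t+1) = A x(t) + B u(t) with a single control
#' element k (B = e_k), average controllability is Trace(W_K) of the
#' controllability Gramian W_K = sum_tau A^tau B B' A^tau. The Gramian
#' solves the discrete Lyapunov equation W - A W A' = B B'; for symmetric
#' stable A the solve is performed in the eigenbasis, which gives
#' Trace(W_K) = sum_i V[k,i]^2 / (1 - lambda_i^2) for each element k.
#'
#' @param system_matrix symmetric matrix with spectral radius < 1 (see
#'   [stabilize()]).
#' @param elements integer indices of the control elements to evaluate one
#'   at a time (default: all).
#' @param control_set optional integer vector: instead of per-element
#'   values, return the single Trace(W_K) for the multi-element control
#'   set K (B has one canonical-vector column per member).
#' @return numeric vector of Trace(W_K) per element (each >= 1), or a
#'   single number if `control_set` is given.
#' @examples
#' A <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
#' average_controllability(A, 1)  # 4/3
#' @export
average_controllability <- function(system_matrix, elements = NULL,
                                    control_set = NULL) {
  A <- as.matrix(system_matrix)
  sr <- spectral_radius(A)
  if (sr >= 1) {
    stop("system is not stable: spectral radius = ", format(sr),
         " >= 1; apply stabilize() first")
  }
  eg <- eigen(A, symmetric = TRUE)
  g <- 1 / (1 - eg$values^2)
  # Trace(W_{e_k}) = sum_i V[k,i]^2 * g_i; additive over control-set members
  per_element <- as.vector((eg$vectors^2) %*% g)
  if (!is.null(control_set)) {
    stopifnot(length(control_set) >= 1,
              all(control_set >= 1 & control_set <= nrow(A)))
    return(sum(per_element[control_set]))
  }
  if (is.null(elements)) elements <- seq_len(nrow(A))
  stopifnot(all(elements >= 1 & elements <= nrow(A)))
  per_element[elements]
}

#' Modal controllability of every element
#'
#' phi_k = sum_j (1 - lambda_j^2) v_kj^2 over an orthonormal
#' eigendecomposition of the (stabilized) symmetric system matrix. phi is
#' well defined under eigenvalue degeneracy because only sums of squared
#' coordinates over an orthonormal basis of each eigenspace enter.
#'
#' @param system_matrix symmetric matrix, typically stabilized so all
#'   |lambda| <= 1 and phi lies in [0, 1].
#' @return numeric vector phi, one value per element; satisfies
#'   sum(phi) == M - sum(lambda^2).
#' @export
modal_controllability <- function(system_matrix) {
  A <- as.matrix(system_matrix)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-8) {
    stop("modal_controllability() requires a square symmetric matrix")
  }
  eg <- eigen(A, symmetric = TRUE)
  as.vector((eg$vectors^2) %*% (1 - eg$values^2))
}

new_controllability_profile <- function(ac, mc, eigenvalues,
                                        stabilization_factor, level,
                                        element_ids = NULL) {
  structure(list(ac = ac, mc = mc, eigenvalues = eigenvalues,
                 stabilization_factor = stabilization_factor,
                 level = level, element_ids = element_ids),
            class = "controllability_profile")
}

#' @exportS3Method base::print
print.controllability_profile <- function(x, ...) {
  cat(sprintf("controllability_profile (%s level): %d elements\n",
              x$level, length(x$ac)))
  cat(sprintf("  AC range [%.4g, %.4g], MC range [%.4g, %.4g]\n",
              min(x$ac), max(x$ac), min(x$mc), max(x$mc)))
  cat(sprintf("  stabilization factor %.6g\n", x$stabilization_factor))
  invisible(x)
}

#' Node-level average and modal controllability of a connectome
#'
#' Stabilizes the adjacency matrix once, then computes average
#' controllability for each node as a single control point and modal
#' controllability for all nodes.
#'
#' @param connectome a [node_connectome()].
#' @return A `controllability_profile` with `ac`, `mc`, `eigenvalues` of
#'   the stabilized system, `stabilization_factor`, and `level = "node"`.
#' @export
node_controllability <- function(connectome) {
  stopifnot_connectome(connectome)
  st <- stabilize(connectome$adjacency)
  eg_vals <- eigen(st$system_matrix, symmetric = TRUE, only.values = TRUE)$values
  new_controllability_profile(
    ac = average_controllability(st$system_matrix),
    mc = modal_controllability(st$system_matrix),
    eigenvalues = eg_vals,
    stabilization_factor = st$stabilization_factor,
    level = "node",
    element_ids = connectome$node_labels)
}

#' Edge-level average and modal controllability (eAC / eMC)
#'
#' Stabilizes the line-graph adjacency once; eAC for each edge is the
#' average controllability with that edge as the single control input,
#' eMC is the modal controllability of every edge.
#'
#' @param edge_net an [edge_network()].
#' @return A `controllability_profile` with `level = "edge"`; empty
#'   vectors when the network has no edges.
#' @export
edge_controllability <- function(edge_net) {
  if (!inherits(edge_net, "edge_network")) stop("expected an edge_network")
  L <- nrow(edge_net$edge_list)
  if (L == 0) {
    return(new_controllability_profile(numeric(0), numeric(0), numeric(0),
                                       1, "edge"))
  }
  st <- stabilize(edge_net$edge_adjacency)
  eg_vals <- eigen(st$system_matrix, symmetric = TRUE, only.values = TRUE)$values
  ids <- paste0(edge_net$edge_list$i, "-", edge_net$edge_list$j)
  new_controllability_profile(
    ac = average_controllability(st$system_matrix),
    mc = modal_controllability(st$system_matrix),
    eigenvalues = eg_vals,
    stabilization_factor = st$stabilization_factor,
    level = "edge",
    element_ids = ids)
}

#' Per-element controllability table
#'
#' @param profile a `controllability_profile`.
#' @return data frame with element identifier, `ac`, `mc`.
#' @export
controllability_table <- function(profile) {
  stopifnot(inherits(profile, "controllability_profile"))
  data.frame(element = profile$element_ids %||% seq_along(profile$ac),
             ac = profile$ac, mc = profile$mc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
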