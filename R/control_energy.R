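#' Stabilize a symmetric matrix for continuous-time dynamics
#'
#' Rescales by 1/(1 + lambda_max) and then shifts by -I, so that the
#' continuous system dx/dt = A x has all eigenvalues strictly negative.
#' Both steps are configurable; the identity shift is the convention used
#' throughout the control-energy literature on brain networks.
#'
#' @param raw_matrix symmetric numeric matrix.
#' @param rescale divide by 1 + lambda_max first (default TRUE).
#' @param shift subtract the identity (default TRUE).
#' @return list with `system_matrix`, `stabilization_factor`, `shifted`.
#' @export
stabilize_continuous <- function(raw_matrix, rescale = TRUE, shift = TRUE) {
  st <- if (rescale) stabilize(raw_matrix) else
    list(system_matrix = as.matrix(raw_matrix), stabilization_factor = 1)
  A <- st$system_matrix
  if (shift) A <- A - diag(nrow(A))
  list(system_matrix = A, stabilization_factor = st$stabilization_factor,
       shifted = shift)
}

#' Define a minimum-energy state-transition task
#'
#' Specifies the continuous-time optimal control problem: drive
#' dx/dt = A x + B u from x(0) = x0 to x(T) = xT while minimizing the
#' integral of the state-tracking cost |xT - x(t)|^2 plus rho |u(t)|^2.
#'
#' @param system_matrix M x M (stabilized) system matrix A.
#' @param x0 initial state (default: zero, the resting baseline).
#' @param xT target state, length M.
#' @param control_mask integer indices of controlled elements defining B
#'   (columns are canonical vectors); default all elements (B = I).
#' @param horizon control horizon T (default 1).
#' @param n_steps number of integration steps (default 1000, i.e. step
#'   size T/1000 = 0.001 at the default horizon).
#' @param rho positive input-energy penalty (default 1).
#' @return An object of class `control_task`.
#' @export
control_task <- function(system_matrix, xT, x0 = NULL, control_mask = NULL,
                         horizon = 1, n_steps = 1000, rho = 1) {
  A <- as.matrix(system_matrix)
  M <- nrow(A)
  stopifnot(ncol(A) == M, length(xT) == M,
            horizon > 0, n_steps >= 2, rho > 0)
  if (is.null(x0)) x0 <- numeric(M)
  stopifnot(length(x0) == M)
  if (is.null(control_mask)) control_mask <- seq_len(M)
  control_mask <- as.integer(control_mask)
  stopifnot(length(control_mask) >= 1,
            all(control_mask >= 1 & control_mask <= M))
  structure(list(system_matrix = A, x0 = as.numeric(x0),
                 xT = as.numeric(xT), control_mask = control_mask,
                 horizon = horizon, n_steps = as.integer(n_steps),
                 rho = rho),
            class = "control_task")
}

#' Solve the minimum-energy optimal control problem
#'
#' Applies the Pontryagin minimum principle to the linear-quadratic task:
#' the optimal input is u* = -B' p* / (2 rho), where the state x and
#' costate p jointly satisfy the linear two-point boundary-value system
#' dx/dt = A x - B B' p / (2 rho), dp/dt = -2 x - A' p + 2 xT. The
#' augmented (state, costate, constant) system is propagated in closed
#' form with a matrix exponential per grid step; the unknown initial
#' costate p(0) is obtained from a linear solve that enforces x(T) = xT.
#'
#' @param task a [control_task()].
#' @param terminal_tol relative terminal error above which a warning is
#'   issued (default 1e-4).
#' @return An object of class `energy_result`: list with `times` (length
#'   n_steps + 1 grid), `state_trajectory`, `costate_trajectory`
#'   ((n_steps+1) x M), `input_trajectory` ((n_steps+1) x M, zero columns
#'   for uncontrolled elements), `element_energy` (length M, trapezoidal
#'   integral of u_k^2), `total_energy`, `terminal_error` (relative, or
#'   absolute when |xT| = 0), and the task.
#' @export
solve_optimal_control <- function(task, terminal_tol = 1e-4) {
  stopifnot(inherits(task, "control_task"))
  A <- task$system_matrix
  M <- nrow(A)
  B <- diag(M)[, task$control_mask, drop = FALSE]
  S <- tcrossprod(B) / (2 * task$rho)   # B B' / (2 rho)
  # augmented generator over z = (x, p, 1)
  Mbig <- matrix(0, 2 * M + 1, 2 * M + 1)
  Mbig[1:M, 1:M] <- A
  Mbig[1:M, (M + 1):(2 * M)] <- -S
  Mbig[(M + 1):(2 * M), 1:M] <- -2 * diag(M)
  Mbig[(M + 1):(2 * M), (M + 1):(2 * M)] <- -t(A)
  Mbig[(M + 1):(2 * M), 2 * M + 1] <- 2 * task$xT

  ET <- as.matrix(Matrix::expm(Mbig * task$horizon))
  Exx <- ET[1:M, 1:M, drop = FALSE]
  Exp <- ET[1:M, (M + 1):(2 * M), drop = FALSE]
  Exc <- ET[1:M, 2 * M + 1]
  rhs <- task$xT - Exx %*% task$x0 - Exc
  p0 <- tryCatch({
    if (rcond(Exp) < 1e-12) stop("ill-conditioned")
    solve(Exp, rhs)
  }, error = function(e) {
    warning("boundary solve ill-conditioned (target may be hard to ",
            "reach exactly); using least-squares costate")
    qr.solve(Exp, rhs)
  })

  dt <- task$horizon / task$n_steps
  Ed <- as.matrix(Matrix::expm(Mbig * dt))
  z <- c(task$x0, as.numeric(p0), 1)
  Z <- matrix(0, task$n_steps + 1, 2 * M + 1)
  Z[1, ] <- z
  for (s in seq_len(task$n_steps)) {
    z <- Ed %*% z
    Z[s + 1, ] <- z
  }
  X <- Z[, 1:M, drop = FALSE]
  P <- Z[, (M + 1):(2 * M), drop = FALSE]
  Uc <- -P[, task$control_mask, drop = FALSE] / (2 * task$rho)  # u = -B'p/(2rho)
  U <- matrix(0, task$n_steps + 1, M)
  U[, task$control_mask] <- Uc

  # trapezoidal integral of u_k(t)^2 on the uniform grid
  U2 <- U^2
  w <- rep(dt, task$n_steps + 1)
  w[c(1, task$n_steps + 1)] <- dt / 2
  element_energy <- as.vector(w %*% U2)

  xT_norm <- sqrt(sum(task$xT^2))
  term_res <- sqrt(sum((X[task$n_steps + 1, ] - task$xT)^2))
  terminal_error <- if (xT_norm > 0) term_res / xT_norm else term_res
  if (terminal_error > terminal_tol) {
    warning(sprintf("terminal error %.3g exceeds tolerance %.3g",
                    terminal_error, terminal_tol))
  }
  structure(list(times = seq(0, task$horizon, length.out = task$n_steps + 1),
                 state_trajectory = X, costate_trajectory = P,
                 input_trajectory = U, element_energy = element_energy,
                 total_energy = sum(element_energy),
                 terminal_error = terminal_error, task = task),
            class = "energy_result")
}

#' @exportS3Method base::print
print.energy_result <- function(x, ...) {
  cat(sprintf("energy_result: M = %d, T = %g, %d steps\n",
              ncol(x$state_trajectory), x$task$horizon, x$task$n_steps))
  cat(sprintf("  total energy %.6g, terminal error %.3g\n",
              x$total_energy, x$terminal_error))
  invisible(x)
}

#' Energy to activate a set of edges in the line graph
#'
#' Builds the activation target: 1 on each target edge ("activated") and 0
#' elsewhere, with the resting baseline x(0) = 0, and solves the
#' minimum-energy problem on the continuously stabilized line-graph
#' adjacency. The normalized energy divides the total by the number of
#' target edges (the network size), making energies comparable across
#' canonical networks of different sizes.
#'
#' @param edge_net an [edge_network()].
#' @param target_edges integer indices (into the edge list) of edges to
#'   activate.
#' @param horizon,n_steps,rho,control_mask forwarded to [control_task()].
#' @param rescale,shift forwarded to [stabilize_continuous()].
#' @return list with `result` (the [solve_optimal_control()] output, NULL
#'   for an empty target), `per_edge_energy`, `total_energy`,
#'   `normalized_energy`, `target_edges`.
#' @export
network_activation_energy <- function(edge_net, target_edges, horizon = 1,
                                      n_steps = 1000, rho = 1,
                                      control_mask = NULL, rescale = TRUE,
                                      shift = TRUE) {
  if (!inherits(edge_net, "edge_network")) stop("expected an edge_network")
  L <- nrow(edge_net$edge_list)
  target_edges <- as.integer(target_edges)
  if (length(target_edges) == 0) {
    warning("empty target edge set: activation energy is 0")
    return(list(result = NULL, per_edge_energy = numeric(L),
                total_energy = 0, normalized_energy = 0,
                target_edges = integer(0)))
  }
  stopifnot(all(target_edges >= 1 & target_edges <= L))
  st <- stabilize_continuous(edge_net$edge_adjacency, rescale, shift)
  xT <- numeric(L)
  xT[target_edges] <- 1
  task <- control_task(st$system_matrix, xT = xT, control_mask = control_mask,
                       horizon = horizon, n_steps = n_steps, rho = rho)
  res <- solve_optimal_control(task)
  list(result = res, per_edge_energy = res$element_energy,
       total_energy = res$total_energy,
       normalized_energy = res$total_energy / length(target_edges),
       target_edges = target_edges)
}

#' Decompose element energies by canonical network pair
#'
#' Sums the per-element energies within each network-pair label (e.g., the
#' 28 within/between pairs of 7 canonical networks); the pair sums add up
#' to the total energy exactly.
#'
#' @param element_energy numeric vector of per-element energies, or an
#'   `energy_result` (its `element_energy` is used).
#' @param pair_labels character/factor labels, one per element.
#' @return data frame with columns `pair` and `energy`, sorted by label.
#' @export
decompose_energy_by_pairs <- function(element_energy, pair_labels) {
  if (inherits(element_energy, "energy_result")) {
    element_energy <- element_energy$element_energy
  }
  if (length(pair_labels) != length(element_energy)) {
    stop("pair_labels length != number of elements")
  }
  if (anyNA(pair_labels)) {
    stop("unlabeled element(s) at index: ",
         paste(utils::head(which(is.na(pair_labels)), 5), collapse = ", "))
  }
  sums <- tapply(element_energy, as.character(pair_labels), sum)
  data.frame(pair = names(sums), energy = as.numeric(sums),
             row.names = NULL)
}
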