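# Shared fixtures and independent oracles used across the suite.

# Random sparse weighted symmetric connectome with log-normal weights.
random_connectome <- function(n, density = 0.3, seed = 1,
                              meanlog = -1, sdlog = 0.7) {
  set.seed(seed)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- stats::runif(length(ut)) < density
  A[ut[on]] <- stats::rlnorm(sum(on), meanlog, sdlog)
  A <- A + t(A)
  node_connectome(A)
}

# Brute-force line-graph adjacency: explicit loop over edge pairs,
# checking shared endpoints (independent of the incidence-matrix path).
oracle_edge_adjacency <- function(edge_list) {
  L <- nrow(edge_list)
  AE <- matrix(0, L, L)
  if (L < 2) return(AE)
  for (a in seq_len(L - 1)) {
    for (b in (a + 1):L) {
      shared <- length(intersect(c(edge_list$i[a], edge_list$j[a]),
                                 c(edge_list$i[b], edge_list$j[b])))
      if (shared == 1) {
        AE[a, b] <- AE[b, a] <- sqrt(edge_list$w[a]) * sqrt(edge_list$w[b])
      }
    }
  }
  AE
}

# Truncated Gramian series oracle: Trace(W) = sum_tau |A^tau e_k|^2.
oracle_ac_series <- function(A, k, tau_max = 1e4) {
  v <- numeric(nrow(A))
  v[k] <- 1
  total <- 1
  for (tau in seq_len(tau_max)) {
    v <- A %*% v
    term <- sum(v^2)
    total <- total + term
    if (term < 1e-18) break
  }
  total
}

# Independent optimal-control oracle: solves the state/costate boundary
# value problem by linear shooting with a dense adaptive ODE integrator
# (deSolve), then integrates |u|^2 on a fine grid. Completely independent
# of the matrix-exponential propagation used by the package.
oracle_energy_bvp <- function(A, B, x0, xT, horizon = 1, rho = 1,
                              n_grid = 20000) {
  M <- nrow(A)
  deriv <- function(t, z, parms) {
    x <- z[1:M]
    p <- z[(M + 1):(2 * M)]
    u <- -crossprod(B, p) / (2 * rho)
    dx <- A %*% x + B %*% u
    dp <- 2 * (xT - x) - crossprod(A, p)
    list(c(dx, dp))
  }
  shoot <- function(p0) {
    out <- deSolve::ode(c(x0, p0), c(0, horizon), deriv, NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-11)
    out[nrow(out), 1 + (1:M)]
  }
  base <- shoot(numeric(M))
  J <- matrix(0, M, M)
  for (i in seq_len(M)) {
    e <- numeric(M); e[i] <- 1
    J[, i] <- shoot(e) - base
  }
  p0 <- solve(J, xT - base)
  times <- seq(0, horizon, length.out = n_grid + 1)
  out <- deSolve::ode(c(x0, p0), times, deriv, NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-11)
  P <- out[, 1 + M + (1:M), drop = FALSE]
  U <- -P %*% B / (2 * rho)
  dt <- horizon / n_grid
  w <- rep(dt, n_grid + 1); w[c(1, n_grid + 1)] <- dt / 2
  list(energy = sum(w * rowSums(U^2)),
       x_final = out[nrow(out), 1 + (1:M)],
       p0 = p0)
}

# Forward re-simulation of a returned input trajectory through
# dx/dt = A x + B u(t) with an independent adaptive integrator.
oracle_forward_sim <- function(A, B, times, U_controlled, x0) {
  u_funs <- lapply(seq_len(ncol(U_controlled)), function(j) {
    stats::approxfun(times, U_controlled[, j], rule = 2)
  })
  deriv <- function(t, x, parms) {
    u <- vapply(u_funs, function(f) f(t), numeric(1))
    list(as.numeric(A %*% x + B %*% u))
  }
  out <- deSolve::ode(x0, c(0, max(times)), deriv, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  out[nrow(out), -1]
}

# Ring graph on n nodes: its line graph is again a ring of n edges.
ring_connectome <- function(n, w = 1) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    A[i, j] <- A[j, i] <- w
  }
  node_connectome(A)
}
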