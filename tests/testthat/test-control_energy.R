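test_that("trivial transitions cost nothing and cost scales quadratically", {
  A <- stabilize_continuous(random_connectome(5, density = 0.6,
                                              seed = 1)$adjacency)$system_matrix
  # x0 = xT = 0 -> no input needed
  res0 <- solve_optimal_control(control_task(A, xT = numeric(5),
                                             n_steps = 200))
  expect_equal(res0$total_energy, 0, tolerance = 1e-20)
  expect_true(all(res0$input_trajectory == 0))

  # doubling the target quadruples the energy (linear dynamics,
  # quadratic cost)
  xT <- c(1, 0, 1, 0, 0)
  e1 <- solve_optimal_control(control_task(A, xT = xT, n_steps = 500))
  e2 <- solve_optimal_control(control_task(A, xT = 2 * xT, n_steps = 500))
  expect_equal(e2$total_energy / e1$total_energy, 4, tolerance = 1e-6)

  expect_equal(e1$total_energy, sum(e1$element_energy))
  expect_true(all(e1$element_energy >= 0))
})

test_that("scalar task matches the independent BVP integrator", {
  A <- matrix(-1, 1, 1)
  res <- solve_optimal_control(control_task(A, xT = 1, n_steps = 5000))
  orc <- oracle_energy_bvp(A, diag(1), 0, 1)
  expect_equal(res$total_energy, orc$energy, tolerance = 1e-6)
  expect_lt(res$terminal_error, 1e-6)
})

test_that("6-element ring line graph matches the BVP oracle", {
  en <- edge_network(ring_connectome(6))
  expect_equal(nrow(en$edge_list), 6)
  st <- stabilize_continuous(en$edge_adjacency)
  res <- network_activation_energy(en, target_edges = 1, n_steps = 5000)
  orc <- oracle_energy_bvp(st$system_matrix, diag(6), numeric(6),
                           c(1, rep(0, 5)))
  expect_equal(res$total_energy, orc$energy, tolerance = 1e-6)

  # symmetric single-edge targets on a vertex-transitive ring cost the same
  res2 <- network_activation_energy(en, target_edges = 4, n_steps = 500)
  res1 <- network_activation_energy(en, target_edges = 1, n_steps = 500)
  expect_equal(res1$total_energy, res2$total_energy, tolerance = 1e-8)
})

test_that("forward re-simulation of u* reaches the target", {
  con <- random_connectome(8, density = 0.5, seed = 11)
  en <- edge_network(con)
  L <- nrow(en$edge_list)
  st <- stabilize_continuous(en$edge_adjacency)
  xT <- as.numeric(seq_len(L) %% 3 == 0)
  task <- control_task(st$system_matrix, xT = xT, n_steps = 1000)
  res <- solve_optimal_control(task)
  x_end <- oracle_forward_sim(st$system_matrix, diag(L), res$times,
                              res$input_trajectory, numeric(L))
  expect_lt(sqrt(sum((x_end - xT)^2)) / sqrt(sum(xT^2)), 1e-4)
  expect_lt(res$terminal_error, 1e-6)
})

test_that("energy is invariant under simultaneous element permutation", {
  con <- random_connectome(7, density = 0.6, seed = 21)
  en <- edge_network(con)
  L <- nrow(en$edge_list)
  st <- stabilize_continuous(en$edge_adjacency)
  xT <- as.numeric(seq_len(L) <= 2)
  e <- solve_optimal_control(control_task(st$system_matrix, xT = xT,
                                          n_steps = 400))
  set.seed(22)
  perm <- sample(L)
  Ap <- st$system_matrix[perm, perm]
  ep <- solve_optimal_control(control_task(Ap, xT = xT[perm],
                                           n_steps = 400))
  expect_equal(ep$total_energy, e$total_energy, tolerance = 1e-8)
  expect_equal(ep$element_energy, e$element_energy[perm], tolerance = 1e-8)
})

test_that("restricted control masks zero out uncontrolled inputs", {
  A <- stabilize_continuous(random_connectome(6, density = 0.7,
                                              seed = 31)$adjacency)$system_matrix
  xT <- rep(c(1, 0), 3)
  res <- solve_optimal_control(control_task(A, xT = xT,
                                            control_mask = c(1, 3, 5),
                                            n_steps = 400))
  expect_true(all(res$input_trajectory[, c(2, 4, 6)] == 0))
  expect_true(all(res$element_energy[c(2, 4, 6)] == 0))
})

test_that("empty activation targets warn and report zero energy", {
  en <- edge_network(ring_connectome(4))
  expect_warning(res <- network_activation_energy(en, integer(0)),
                 "empty target")
  expect_equal(res$total_energy, 0)
  expect_equal(res$normalized_energy, 0)
})

test_that("normalized energy divides by target-network size", {
  en <- edge_network(ring_connectome(5))
  res <- network_activation_energy(en, target_edges = c(1, 3),
                                   n_steps = 300)
  expect_equal(res$normalized_energy, res$total_energy / 2)
})

test_that("pair decomposition conserves total energy", {
  en <- edge_network(random_connectome(8, density = 0.5, seed = 41))
  L <- nrow(en$edge_list)
  res <- network_activation_energy(en, target_edges = seq_len(min(3, L)),
                                   n_steps = 300)
  # all edges one label
  one <- decompose_energy_by_pairs(res$per_edge_energy, rep("all", L))
  expect_equal(one$energy, res$total_energy)

  # 2-label split matches manual grouping and conserves the total
  lab <- rep(c("a", "b"), length.out = L)
  dec <- decompose_energy_by_pairs(res$per_edge_energy, lab)
  expect_equal(sum(dec$energy), res$total_energy, tolerance = 1e-12)
  expect_equal(dec$energy[dec$pair == "a"],
               sum(res$per_edge_energy[lab == "a"]))

  lab[2] <- NA
  expect_error(decompose_energy_by_pairs(res$per_edge_energy, lab),
               "unlabeled")
})
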