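test_that("edge list applies the absence threshold and canonical order", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.5
  A[1, 3] <- A[3, 1] <- 0.0005   # below threshold: treated as absent
  A[2, 3] <- A[3, 2] <- 0.2
  el <- build_edge_list(node_connectome(A))
  expect_equal(el$i, c(1L, 2L))
  expect_equal(el$j, c(2L, 3L))
  expect_equal(el$w, c(0.5, 0.2))
  expect_equal(attr(el, "L"), 2L)

  expect_equal(nrow(build_edge_list(node_connectome(matrix(0, 4, 4)))), 0L)

  el2 <- build_edge_list(node_connectome(matrix(c(0, 1, 1, 0), 2, 2)))
  expect_equal(unname(as.matrix(el2)), matrix(c(1, 2, 1), 1, 3))
})

test_that("invalid adjacency inputs are rejected", {
  expect_error(node_connectome(matrix(1, 3, 4)), "square")
  M <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(node_connectome(M), "asymmetric")
  Mn <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(node_connectome(Mn), "negative weight")
})

test_that("incidence entries are sqrt(w) and reproduce A + D", {
  # single edge of weight 4 on two nodes
  A1 <- matrix(c(0, 4, 4, 0), 2, 2)
  con1 <- node_connectome(A1)
  C1 <- build_incidence(build_edge_list(con1))
  expect_equal(C1, matrix(c(2, 2), 2, 1))
  expect_equal(C1 %*% t(C1), A1 + diag(c(4, 4)), ignore_attr = TRUE)

  # unit triangle: each column two ones, C C' = A + 2 I
  A2 <- matrix(1, 3, 3); diag(A2) <- 0
  con2 <- node_connectome(A2)
  C2 <- build_incidence(build_edge_list(con2))
  expect_true(all(colSums(C2 != 0) == 2))
  expect_true(all(C2 %in% c(0, 1)))
  expect_equal(C2 %*% t(C2), A2 + diag(3) * 2, ignore_attr = TRUE)

  # path with weights (4, 9): shared node carries sqrt of both
  A3 <- matrix(0, 3, 3)
  A3[1, 2] <- A3[2, 1] <- 4; A3[2, 3] <- A3[3, 2] <- 9
  con3 <- node_connectome(A3)
  C3 <- build_incidence(build_edge_list(con3))
  expect_equal(C3[2, ], c(2, 3))
  expect_equal(C3 %*% t(C3), A3 + diag(con3$strength), ignore_attr = TRUE)
})

test_that("incidence identity C C' = A + D holds on random connectomes", {
  for (s in 1:25) {
    con <- random_connectome(sample(5:60, 1), density = runif(1, 0.1, 0.6),
                             seed = s)
    el <- build_edge_list(con)
    C <- build_incidence(el)
    err <- max(abs(C %*% t(C) - (con$adjacency + diag(con$strength))))
    expect_lt(err, 1e-10)
  }
})

test_that("edge adjacency matches the brute-force shared-endpoint oracle", {
  # two disjoint edges -> zero line graph
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 2
  en <- edge_network(node_connectome(A))
  expect_equal(en$edge_adjacency, matrix(0, 2, 2), ignore_attr = TRUE)

  # path weights (4, 9) -> off-diagonal 6
  A2 <- matrix(0, 3, 3)
  A2[1, 2] <- A2[2, 1] <- 4; A2[2, 3] <- A2[3, 2] <- 9
  en2 <- edge_network(node_connectome(A2))
  expect_equal(en2$edge_adjacency, matrix(c(0, 6, 6, 0), 2, 2),
               ignore_attr = TRUE)

  # unit triangle -> all off-diagonal 1
  A3 <- matrix(1, 3, 3); diag(A3) <- 0
  en3 <- edge_network(node_connectome(A3))
  expect_equal(en3$edge_adjacency, matrix(1, 3, 3) - diag(3),
               ignore_attr = TRUE)

  # random graphs agree exactly with the double-loop oracle
  for (s in 1:30) {
    con <- random_connectome(sample(4:20, 1), density = runif(1, 0.1, 0.8),
                             seed = 100 + s)
    en <- edge_network(con)
    expect_identical(unname(en$edge_adjacency),
                     oracle_edge_adjacency(en$edge_list))
  }
})

test_that("line-graph structure is invariant under node relabeling", {
  con <- random_connectome(12, density = 0.4, seed = 7)
  en <- edge_network(con)
  set.seed(8)
  perm <- sample(con$n_nodes)
  Ap <- con$adjacency[perm, perm]
  enp <- edge_network(node_connectome(Ap))
  expect_equal(nrow(enp$edge_list), nrow(en$edge_list))
  # match permuted edges back to original edge indices
  inv <- order(perm)   # inv[new] = old... perm maps new index -> old row
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  orig_keys <- key(en$edge_list$i, en$edge_list$j)
  new_keys <- key(perm[enp$edge_list$i], perm[enp$edge_list$j])
  m <- match(new_keys, orig_keys)
  expect_false(anyNA(m))
  expect_equal(unname(enp$edge_adjacency),
               unname(en$edge_adjacency[m, m]))
})

test_that("feature alignment scatters edges onto the full pair index", {
  expect_equal(nrow(edge_feature_index(120)), 7140)
  con <- random_connectome(10, density = 0.3, seed = 3)
  el <- build_edge_list(con)
  v <- align_edge_features(el$w, el)
  idx <- edge_feature_index(10)
  expect_length(v, 45)
  # every present edge lands on its pair position; absent pairs are 0
  for (r in seq_len(nrow(el))) {
    k <- idx$k[idx$i == el$i[r] & idx$j == el$j[r]]
    expect_equal(v[k], el$w[r])
  }
  expect_equal(sum(v != 0), nrow(el))
  # missing marker variant
  vna <- align_edge_features(el$w, el, missing = NA)
  expect_equal(sum(is.na(vna)), 45 - nrow(el))
})
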