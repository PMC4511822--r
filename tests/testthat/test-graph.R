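complete_cm <- function(n) {
  v <- matrix(1, n, n); diag(v) <- 0
  conn_matrix(v, seq_len(n), weight_kind = "binary")
}

test_that("closed forms on canonical graphs", {
  k5 <- complete_cm(5)
  expect_equal(unname(graph_degree(k5)$per_node), rep(4, 5))
  expect_equal(unname(clustering_coefficient(k5)$per_node), rep(1, 5))
  expect_equal(characteristic_path_length(k5)$L, 1)
  empty <- conn_matrix(matrix(0, 4, 4), 1:4, weight_kind = "binary")
  expect_equal(unname(graph_degree(empty)$per_node), rep(0, 4))
  # star graph: all clustering 0
  v <- matrix(0, 5, 5); v[1, 2:5] <- 1; v <- v + t(v)
  star <- conn_matrix(v, 1:5, weight_kind = "binary")
  expect_equal(unname(clustering_coefficient(star)$per_node), rep(0, 5))
  # path graph on 3 nodes: L = 4/3
  pv <- matrix(0, 3, 3); pv[1, 2] <- pv[2, 3] <- 1; pv <- pv + t(pv)
  p3 <- conn_matrix(pv, 1:3, weight_kind = "binary")
  expect_equal(characteristic_path_length(p3)$L, 4 / 3)
})

test_that("metrics equal brute-force oracles on random graphs", {
  for (draw in 1:30) {
    R <- sample(4:15, 1)
    g <- rand_bin_cm(R, stats::runif(1, 0.15, 0.7), seed = 4000 + draw)
    A <- g$values
    expect_equal(unname(graph_degree(g)$per_node), unname(rowSums(A)))
    expect_equal(unname(clustering_coefficient(g)$per_node),
                 unname(oracle_clustering(A)), tolerance = 1e-12)
    d <- oracle_distances(A)
    if (any(is.finite(d[row(d) != col(d)]))) {
      cpl <- characteristic_path_length(g)
      expect_equal(cpl$L, oracle_char_path_length(A))
      off <- d[row(d) != col(d)]
      expect_equal(cpl$unreachable_frac, mean(!is.finite(off)))
    }
  }
})

test_that("metrics are invariant to node relabeling", {
  g <- rand_bin_cm(9, 0.4, seed = 90)
  perm <- sample(9)
  gp <- conn_matrix(g$values[perm, perm], g$roi_ids[perm],
                    weight_kind = "binary")
  expect_equal(sort(unname(graph_degree(gp)$per_node)),
               sort(unname(graph_degree(g)$per_node)))
  expect_equal(clustering_coefficient(gp)$mean, clustering_coefficient(g)$mean)
  expect_equal(characteristic_path_length(gp)$L,
               characteristic_path_length(g)$L)
})

test_that("null graphs conserve edge count, symmetry and are seeded", {
  g <- rand_bin_cm(12, 0.3, seed = 91)
  m <- sum(g$values) / 2
  nulls <- random_null(g, n = 10, seed = 92)
  expect_length(nulls, 10)
  for (ng in nulls) {
    expect_equal(sum(ng$values) / 2, m)
    expect_equal(ng$values, t(ng$values))
    expect_true(all(diag(ng$values) == 0))
  }
  expect_identical(lapply(random_null(g, 5, seed = 7), `[[`, "values"),
                   lapply(random_null(g, 5, seed = 7), `[[`, "values"))
  expect_error(random_null(g, n = 0), ">= 1")
})

test_that("null edge placement is uniform over pairs", {
  g <- rand_bin_cm(8, 0.3, seed = 93)
  nulls <- random_null(g, n = 2000, seed = 94)
  freq <- Reduce(`+`, lapply(nulls, `[[`, "values")) / 2000
  ut <- freq[upper.tri(freq)]
  m <- sum(g$values) / 2
  p_expect <- m / length(ut)
  ci <- 4 * sqrt(p_expect * (1 - p_expect) / 2000)
  expect_true(all(abs(ut - p_expect) < ci + 0.02))
})

test_that("small-worldness components and determinism", {
  # ring lattice: high clustering relative to matched random graphs
  R <- 24
  v <- matrix(0, R, R)
  for (i in seq_len(R)) for (s in 1:2) {
    j <- ((i - 1 + s) %% R) + 1
    v[i, j] <- 1; v[j, i] <- 1
  }
  ring <- conn_matrix(v, seq_len(R), weight_kind = "binary")
  sw <- small_worldness(ring, n_null = 10, seed = 95)
  expect_gt(sw$normalized["clustering"], 2)
  expect_identical(small_worldness(ring, seed = 96)$sigma,
                   small_worldness(ring, seed = 96)$sigma)
  expect_equal(sw$sigma, (sw$C / sw$C_null) / (sw$L / sw$L_null))
})

test_that("modularity: two disjoint 4-cliques are optimally split, Q = 0.5", {
  v <- matrix(0, 8, 8)
  v[1:4, 1:4] <- 1; v[5:8, 5:8] <- 1; diag(v) <- 0
  g <- conn_matrix(v, 1:8, weight_kind = "binary")
  mod <- graph_modularity(g, seed = 97)
  expect_equal(mod$Q, 0.5)
  expect_length(unique(mod$partition[1:4]), 1)
  expect_length(unique(mod$partition[5:8]), 1)
  expect_false(mod$partition[1] == mod$partition[5])
  # exhaustive search over all partitions of 8 nodes confirms the optimum
  best <- max(vapply(oracle_partitions(8),
                     function(p) modularity_q(v, p), 0))
  expect_equal(mod$Q, best)
  # complete graph: trivial single community, Q = 0
  k <- complete_cm(6)
  expect_equal(modularity_q(k$values, rep(1L, 6)), 0)
})

test_that("greedy modularity never beats exhaustive search on small graphs", {
  for (draw in 1:5) {
    g <- rand_bin_cm(7, 0.4, seed = 5000 + draw)
    if (sum(g$values) == 0) next
    mod <- graph_modularity(g, seed = draw)
    # Q evaluation agrees with the direct formula
    expect_equal(mod$Q, modularity_q(g$values, mod$partition))
    best <- max(vapply(oracle_partitions(7),
                       function(p) modularity_q(g$values, p), 0))
    expect_lte(mod$Q, best + 1e-12)
  }
})

test_that("directed matrices are rejected where undirected metrics apply", {
  v <- matrix(0, 3, 3); v[1, 2] <- 1
  e <- conn_matrix(v, 1:3, directed = TRUE, weight_kind = "binary")
  expect_error(graph_degree(e), "undirected")
  degs <- graph_degree_directed(e)
  expect_equal(unname(degs$out_degree), c(1, 0, 0))
  expect_equal(unname(degs$in_degree), c(0, 1, 0))
})
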