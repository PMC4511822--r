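test_that("binarization rules: positive count and p threshold", {
  v <- matrix(0, 3, 3); v[1, 2] <- v[2, 1] <- 3; v[1, 3] <- v[3, 1] <- 17
  cm <- conn_matrix(v, 1:3, modality = "s", weight_kind = "count")
  b <- binarize(cm, "positive_count")
  expect_equal(unname(b$values[1, ]), c(0, 1, 1))
  p1 <- matrix(1, 3, 3)
  expect_true(all(binarize(cm, "p_threshold", p_matrix = p1)$values == 0))
  expect_error(binarize(cm, "p_threshold"), "p_matrix")
  # elementwise brute-force comparison on a random count matrix
  set.seed(81)
  rv <- matrix(stats::rpois(36, 1), 6); rv <- rv + t(rv); diag(rv) <- 0
  rcm <- conn_matrix(rv, 1:6, weight_kind = "count")
  expect_equal(binarize(rcm)$values > 0, rcm$values > 0)
})

test_that("mean and variance matrices are the elementwise moments", {
  mk <- function(a) {
    v <- matrix(0, 2, 2); v[1, 2] <- v[2, 1] <- a
    conn_matrix(v, 1:2)
  }
  st <- subject_stack(list(mk(4), mk(6)))
  expect_equal(mean_cm(st)$values[1, 2], 5)
  expect_equal(variance_cm(st)$values[1, 2], 1)
  expect_equal(mean_cm(subject_stack(list(mk(3))))$values[1, 2], 3)
  set.seed(82)
  mats <- lapply(1:10, function(i) {
    v <- matrix(stats::rnorm(25), 5); v <- v + t(v); diag(v) <- 0
    conn_matrix(v, 1:5)
  })
  got <- mean_cm(subject_stack(mats))$values
  want <- Reduce(`+`, lapply(mats, `[[`, "values")) / 10
  expect_equal(got, want)
})

test_that("robustness is the fraction of subjects showing each connection", {
  edge_in <- function(present) {
    v <- matrix(0, 2, 2)
    if (present) v[1, 2] <- v[2, 1] <- 1
    conn_matrix(v, 1:2, weight_kind = "binary")
  }
  # present in 1 of 10 subjects -> 0.1; in 9 of 10 -> 0.9
  st1 <- subject_stack(lapply(1:10, function(i) edge_in(i == 1)))
  expect_equal(robustness_cm(st1)$values[1, 2], 0.1)
  st9 <- subject_stack(lapply(1:10, function(i) edge_in(i <= 9)))
  expect_equal(robustness_cm(st9)$values[1, 2], 0.9)
  # idempotence: identical binary matrices reproduce themselves
  M <- rand_bin_cm(6, 0.4, seed = 83)
  stM <- subject_stack(lapply(1:7, function(i) M))
  expect_equal(robustness_cm(stM)$values, M$values)
  notbin <- conn_matrix(matrix(c(0, 2, 2, 0), 2), 1:2)
  expect_error(robustness_cm(subject_stack(list(notbin))), "binary")
})

test_that("combined matrix masks the mean by strict robustness threshold", {
  mk <- function(m, r) {
    mean_m <- conn_matrix(matrix(c(0, m, m, 0), 2), 1:2)
    rob <- conn_matrix(matrix(c(0, r, r, 0), 2), 1:2,
                       weight_kind = "probability")
    combined_cm(mean_m, rob, tau = 0.8)$values[1, 2]
  }
  expect_equal(mk(12, 0.9), 12)
  expect_equal(mk(12, 0.7), 0)
  expect_equal(mk(12, 0.8), 0)  # strict inequality at the boundary
  # contraction: |combined| <= |mean| elementwise
  set.seed(84)
  v <- matrix(stats::rnorm(49), 7); v <- v + t(v); diag(v) <- 0
  meanm <- conn_matrix(v, 1:7)
  rv <- matrix(stats::runif(49), 7); rv <- (rv + t(rv)) / 2; diag(rv) <- 0
  rob <- conn_matrix(rv, 1:7, weight_kind = "probability")
  cmb <- combined_cm(meanm, rob)
  expect_true(all(abs(cmb$values) <= abs(meanm$values)))
})

test_that("hybrid sf matrix is the elementwise product", {
  set.seed(85)
  sv <- matrix(stats::rpois(36, 3), 6); sv <- sv + t(sv); diag(sv) <- 0
  fv <- matrix(stats::runif(36, -1, 1), 6); fv <- (fv + t(fv)) / 2; diag(fv) <- 0
  s <- conn_matrix(sv, 1:6, modality = "s", weight_kind = "count")
  f <- conn_matrix(fv, 1:6, modality = "f", weight_kind = "correlation")
  sf <- hybrid_sf(s, f)
  want <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) want[i, j] <- sv[i, j] * fv[i, j]
  expect_equal(unname(sf$values), want)
  expect_identical(sf$modality, "sf")
  zero <- conn_matrix(matrix(0, 6, 6), 1:6)
  expect_true(all(hybrid_sf(s, zero)$values == 0))
  s3 <- conn_matrix(matrix(0, 3, 3), 1:3)
  expect_error(hybrid_sf(s3, f), "ROI")
  # s(i,j)=3, f(i,j)=0.5 -> 1.5
  s1 <- conn_matrix(matrix(c(0, 3, 3, 0), 2), 1:2)
  f1 <- conn_matrix(matrix(c(0, 0.5, 0.5, 0), 2), 1:2)
  expect_equal(hybrid_sf(s1, f1)$values[1, 2], 1.5)
})

test_that("direct/mediated decomposition partitions the functional edges", {
  s <- rand_bin_cm(5, 0.5, seed = 86)
  f <- rand_bin_cm(5, 0.5, seed = 87)
  dec <- decompose_direct_mediated(s, f)
  # edge in both -> direct; f only -> mediated; s only -> neither
  both <- s$values == 1 & f$values == 1
  fonly <- f$values == 1 & s$values == 0
  sonly <- s$values == 1 & f$values == 0
  expect_true(all(dec$direct$values[both] == 1))
  expect_true(all(dec$mediated$values[fonly] == 1))
  expect_true(all(dec$direct$values[sonly] == 0 & dec$mediated$values[sonly] == 0))
  # partition law on many random pairs
  for (draw in 1:100) {
    s <- rand_bin_cm(6, stats::runif(1, 0.2, 0.8), seed = 1000 + draw)
    f <- rand_bin_cm(6, stats::runif(1, 0.2, 0.8), seed = 2000 + draw)
    dec <- decompose_direct_mediated(s, f)
    expect_equal(dec$direct$values + dec$mediated$values, f$values)
    expect_true(all(dec$direct$values * dec$mediated$values == 0))
  }
})

test_that("mediated path reproduces the canonical frontal chain", {
  # right rostral middle frontal connects to the left one only through the
  # superior frontal gyri: the fewest-intermediates path has 4 regions
  nm <- c("rostralmiddlefrontal_R", "superiorfrontal_R", "superiorfrontal_L",
          "rostralmiddlefrontal_L", "insula_L", "insula_R")
  v <- matrix(0, 6, 6)
  link <- function(i, j) { v[i, j] <<- 1; v[j, i] <<- 1 }
  link(1, 2); link(2, 3); link(3, 4); link(5, 6); link(2, 5)
  g <- conn_matrix(v, 1:6, modality = "s", weight_kind = "binary",
                   roi_names = nm)
  path <- mediated_path(g, "rostralmiddlefrontal_R", "rostralmiddlefrontal_L")
  expect_equal(path, c("rostralmiddlefrontal_R", "superiorfrontal_R",
                       "superiorfrontal_L", "rostralmiddlefrontal_L"))
  expect_length(path, 4)
  # adjacent source/target -> 2-region path
  expect_length(mediated_path(g, "insula_L", "insula_R"), 2)
  # disconnected -> NULL
  v2 <- matrix(0, 4, 4); v2[1, 2] <- v2[2, 1] <- 1
  g2 <- conn_matrix(v2, 1:4, weight_kind = "binary")
  expect_null(mediated_path(g2, 1, 3))
  expect_error(mediated_path(g, "nope", "insula_L"), "unknown ROI")
  expect_error(mediated_path(g, 1, 1), "differ")
})

test_that("mediated path length matches exhaustive enumeration", {
  for (draw in 1:25) {
    R <- sample(5:12, 1)
    g <- rand_bin_cm(R, 0.25, seed = 3000 + draw)
    src <- 1; tgt <- R
    got <- mediated_path(g, src, tgt)
    want <- oracle_shortest_path_nodes(g$values, src, tgt)
    if (is.na(want)) {
      expect_null(got)
    } else {
      expect_length(got, want)
      # returned path is a real path in the graph
      idx <- match(got, g$roi_names)
      for (k in seq_len(length(idx) - 1))
        expect_equal(g$values[idx[k], idx[k + 1]], 1)
    }
    # all-shortest mode returns only minimum-length paths including the BFS one
    if (!is.na(want)) {
      alls <- mediated_path(g, src, tgt, all_shortest = TRUE)
      expect_true(all(lengths(alls) == want))
      expect_true(any(vapply(alls, identical, TRUE, got)))
    }
  }
})
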