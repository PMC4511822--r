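# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (igraph, qr-based OLS) they verify.

rand_bin_cm <- function(R, p = 0.3, seed = 1, modality = "custom") {
  set.seed(seed)
  v <- matrix(0, R, R)
  ut <- which(upper.tri(v))
  v[ut] <- stats::rbinom(length(ut), 1, p)
  v <- v + t(v)
  conn_matrix(v, seq_len(R), modality = modality, weight_kind = "binary")
}

# triangles through each node from the adjacency cube
oracle_clustering <- function(A) {
  tri <- diag(A %*% A %*% A) / 2
  k <- rowSums(A)
  ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
}

# all-pairs shortest paths by Floyd-Warshall
oracle_distances <- function(A) {
  R <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(R)) for (i in seq_len(R)) for (j in seq_len(R))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_char_path_length <- function(A) {
  d <- oracle_distances(A)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# all set partitions of n items as restricted-growth strings
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (lab in seq_len(maxlab + 1))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  out
}

# shortest simple-path node count by exhaustive DFS enumeration
oracle_shortest_path_nodes <- function(A, src, tgt) {
  best <- Inf
  rec <- function(u, visited) {
    if (u == tgt) { best <<- min(best, length(visited)); return() }
    if (length(visited) >= best) return()
    for (v in which(A[u, ] > 0)) if (!v %in% visited) rec(v, c(visited, v))
  }
  rec(src, src)
  if (is.finite(best)) best else NA_integer_
}

# OLS through explicit normal equations (independent of qr-based fits)
oracle_gc <- function(x, y, p) {
  Tn <- length(y)
  yt <- y[(p + 1):Tn]
  lag <- function(v, k) v[(p - k + 1):(Tn - k)]
  Xr <- cbind(1, sapply(seq_len(p), function(k) lag(y, k)))
  Xf <- cbind(Xr, sapply(seq_len(p), function(k) lag(x, k)))
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% yt)
    sum((yt - X %*% b)^2)
  }
  rss_r <- rss(Xr); rss_f <- rss(Xf)
  T_eff <- Tn - p
  Fst <- ((rss_r - rss_f) / p) / (rss_f / (T_eff - 2 * p - 1))
  c(gc = log(rss_r / rss_f), F = Fst)
}

# tiny fixture parcellation shared across tests
toy_parc8 <- function() make_toy_parcellation(8)
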