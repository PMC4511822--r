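# Graph-theory metrics over binary (and weighted) connectivity matrices,
# with normalization against edge-count-preserving random null graphs.
# Standard metrics delegate to igraph; the modularity Q of a partition is
# evaluated directly from the e_ii - a_i^2 formula.

as_igraph <- function(cm, weighted = FALSE) {
  igraph::graph_from_adjacency_matrix(
    cm$values, mode = if (cm$directed) "directed" else "undirected",
    weighted = if (weighted) TRUE else NULL, diag = FALSE)
}

require_binary_undirected <- function(cm) {
  stopifnot_conn(cm)
  if (cm$directed) stop("metric defined for undirected matrices; use graph_degree_directed for e-CM")
  if (!is_binary_cm(cm)) stop("metric requires a binary matrix")
  invisible(cm)
}

#' Node degree of a binary undirected graph
#'
#' @param cm binary undirected [conn_matrix()].
#' @return list with `per_node` (named integer vector) and `mean`.
#' @export
graph_degree <- function(cm) {
  require_binary_undirected(cm)
  k <- rowSums(cm$values)
  names(k) <- cm$roi_names
  list(per_node = k, mean = mean(k))
}

#' In/out degree of a directed binary graph
#'
#' @param cm directed binary [conn_matrix()] (e-CM).
#' @return list with named vectors `in_degree`, `out_degree`.
#' @export
graph_degree_directed <- function(cm) {
  stopifnot_conn(cm)
  if (!cm$directed) stop("expected a directed matrix")
  list(in_degree = stats::setNames(colSums(cm$values), cm$roi_names),
       out_degree = stats::setNames(rowSums(cm$values), cm$roi_names))
}

#' Local clustering coefficient
#'
#' Binary triangle definition `C_i = 2 t_i / (k_i (k_i - 1))`; nodes with
#' degree < 2 score 0.
#'
#' @param cm binary undirected [conn_matrix()].
#' @return list with `per_node` and `mean`.
#' @export
clustering_coefficient <- function(cm) {
  require_binary_undirected(cm)
  g <- as_igraph(cm)
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  ci[is.na(ci)] <- 0
  names(ci) <- cm$roi_names
  list(per_node = ci, mean = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest-path length over ordered reachable node pairs; unreachable
#' pairs are excluded and their fraction reported so the exclusion is
#' auditable.
#'
#' @param cm binary undirected [conn_matrix()].
#' @return list with `L` and `unreachable_frac`.
#' @export
characteristic_path_length <- function(cm) {
  require_binary_undirected(cm)
  R <- n_rois(cm)
  if (R < 2) stop("need at least 2 nodes")
  d <- igraph::distances(as_igraph(cm))
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  if (!any(reach)) stop("graph has no reachable pairs")
  list(L = mean(off[reach]), unreachable_frac = mean(!reach))
}

#' Random null graphs preserving edge count and symmetry
#'
#' Each null graph re-draws the same number of edges uniformly on the upper
#' triangle (hence identical node count, edge count and mean degree) and is
#' symmetric with an empty diagonal.
#'
#' @param cm binary undirected [conn_matrix()].
#' @param n number of null graphs (default 10).
#' @param seed RNG seed.
#' @return list of binary [conn_matrix()] objects.
#' @export
random_null <- function(cm, n = 10, seed = 1) {
  require_binary_undirected(cm)
  if (n < 1) stop("n must be >= 1")
  local_seed(seed)
  R <- n_rois(cm)
  ut <- which(upper.tri(cm$values))
  m <- sum(cm$values[ut])
  lapply(seq_len(n), function(i) {
    v <- matrix(0, R, R)
    v[sample(ut, m)] <- 1
    v <- v + t(v)
    conn_matrix(v, cm$roi_ids, modality = cm$modality, weight_kind = "binary",
                roi_names = cm$roi_names)
  })
}

#' Small-worldness and normalized graph indexes
#'
#' Normalizes mean clustering C and characteristic path length L by their
#' averages over random null graphs, and reports
#' `sigma = (C / <C_null>) / (L / <L_null>)` together with the individual
#' normalized ratios (degree, C, L).
#'
#' @param cm binary undirected [conn_matrix()].
#' @param n_null number of null graphs (default 10).
#' @param seed RNG seed.
#' @return list with `sigma`, `C`, `L`, `C_null`, `L_null` and
#'   `normalized` (ratios for degree, clustering, path length).
#' @export
small_worldness <- function(cm, n_null = 10, seed = 1) {
  require_binary_undirected(cm)
  C <- clustering_coefficient(cm)$mean
  L <- characteristic_path_length(cm)$L
  k <- graph_degree(cm)$mean
  nulls <- random_null(cm, n = n_null, seed = seed)
  Cn <- mean(vapply(nulls, function(g) clustering_coefficient(g)$mean, 0))
  Ln <- mean(vapply(nulls, function(g) characteristic_path_length(g)$L, 0))
  kn <- mean(vapply(nulls, function(g) graph_degree(g)$mean, 0))
  if (Cn == 0 || Ln == 0) stop("null-graph clustering or path length is zero")
  list(sigma = (C / Cn) / (L / Ln), C = C, L = L, C_null = Cn, L_null = Ln,
       normalized = c(degree = k / kn, clustering = C / Cn, path_length = L / Ln))
}

#' Modularity partition of a connectivity graph
#'
#' Finds a community partition with the multilevel (Louvain) greedy
#' procedure and evaluates Newman's modularity
#' `Q = sum_i (e_ii - a_i^2)` for that partition directly from the
#' adjacency, where `e_ii` is the fraction of edge weight inside community i
#' and `a_i` its total incident weight fraction.
#'
#' @param cm undirected [conn_matrix()] with nonnegative weights.
#' @param seed RNG seed for the (stochastic) greedy optimization.
#' @return list with `partition` (named integer vector) and `Q`.
#' @export
graph_modularity <- function(cm, seed = 1) {
  stopifnot_conn(cm)
  if (cm$directed) stop("modularity implemented for undirected matrices")
  if (min(cm$values) < 0) stop("modularity requires nonnegative weights")
  local_seed(seed)
  g <- as_igraph(cm, weighted = TRUE)
  comm <- igraph::cluster_louvain(g)
  part <- igraph::membership(comm)
  part <- stats::setNames(as.integer(part), cm$roi_names)
  list(partition = part, Q = modularity_q(cm$values, part))
}

#' Modularity Q of a given partition
#'
#' @param adjacency symmetric nonnegative matrix.
#' @param partition integer community labels, one per node.
#' @return Q value.
#' @export
modularity_q <- function(adjacency, partition) {
  W <- sum(adjacency)
  if (W == 0) return(0)
  q <- 0
  for (cmm in unique(partition)) {
    sel <- partition == cmm
    e_ii <- sum(adjacency[sel, sel]) / W
    a_i <- sum(adjacency[sel, ]) / W
    q <- q + e_ii - a_i^2
  }
  q
}
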