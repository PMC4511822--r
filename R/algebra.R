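# Subject-stack matrix algebra: binarization, group mean / robustness /
# combined matrices, hybrid structural-functional matrices, direct vs.
# mediated decomposition, and the mediated-path search.

#' Subject stack of connectivity matrices
#'
#' @param matrices named list of [conn_matrix()] objects (one per subject)
#'   sharing shape, ROI order, modality and directedness.
#' @param covariates optional data.frame with one row per subject
#'   (`subject_id`, `age`, `sex`, `group`, ...).
#' @return object of class `subject_stack`.
#' @export
subject_stack <- function(matrices, covariates = NULL) {
  if (!length(matrices)) stop("empty subject stack")
  lapply(matrices, stopifnot_conn)
  ref <- matrices[[1]]
  for (m in matrices) {
    check_same_rois(ref, m)
    if (m$directed != ref$directed || m$modality != ref$modality)
      stop("all matrices in a stack must share modality and directedness")
  }
  if (is.null(names(matrices)))
    names(matrices) <- sprintf("S%02d", seq_along(matrices))
  if (!is.null(covariates) && nrow(covariates) != length(matrices))
    stop("covariates must have one row per subject")
  structure(list(subject_ids = names(matrices), matrices = matrices,
                 covariates = covariates), class = "subject_stack")
}

#' @export
print.subject_stack <- function(x, ...) {
  cat(sprintf("<subject_stack> %d subjects, %d ROIs, modality=%s\n",
              length(x$matrices), n_rois(x$matrices[[1]]),
              x$matrices[[1]]$modality))
  invisible(x)
}

#' Binarize a connectivity matrix
#'
#' Rules: `"positive_count"` keeps entries with value > 0 (the fiber-count
#' rule); `"p_threshold"` keeps entries whose p-value (supplied in
#' `p_matrix`) falls below `alpha`.
#'
#' @param cm a [conn_matrix()].
#' @param rule `"positive_count"` or `"p_threshold"`.
#' @param alpha significance level for the p rule.
#' @param p_matrix p-value matrix for the p rule.
#' @return binary [conn_matrix()].
#' @export
binarize <- function(cm, rule = c("positive_count", "p_threshold"),
                     alpha = 0.05, p_matrix = NULL) {
  stopifnot_conn(cm)
  rule <- match.arg(rule)
  if (rule == "positive_count") {
    b <- (cm$values > 0) * 1
  } else {
    if (is.null(p_matrix)) stop("p_threshold rule requires a p_matrix")
    if (!identical(dim(p_matrix), dim(cm$values)))
      stop("p_matrix shape does not match the matrix")
    b <- (p_matrix < alpha) * 1
  }
  diag(b) <- 0
  conn_matrix(b, cm$roi_ids, modality = cm$modality, directed = cm$directed,
              weight_kind = "binary", roi_names = cm$roi_names)
}

#' Group mean connectivity matrix
#'
#' Elementwise arithmetic mean of the subjects' weighted matrices.
#'
#' @param stack a [subject_stack()].
#' @return mean-CM as a [conn_matrix()].
#' @export
mean_cm <- function(stack) {
  vals <- Reduce(`+`, lapply(stack$matrices, `[[`, "values")) /
    length(stack$matrices)
  ref <- stack$matrices[[1]]
  conn_matrix(vals, ref$roi_ids, modality = ref$modality,
              directed = ref$directed, weight_kind = "custom",
              roi_names = ref$roi_names)
}

#' Elementwise variance across a subject stack
#'
#' @param stack a [subject_stack()].
#' @return variance matrix as a [conn_matrix()] (population denominator n).
#' @export
variance_cm <- function(stack) {
  mats <- lapply(stack$matrices, `[[`, "values")
  mu <- Reduce(`+`, mats) / length(mats)
  v <- Reduce(`+`, lapply(mats, function(m) (m - mu)^2)) / length(mats)
  ref <- stack$matrices[[1]]
  conn_matrix(v, ref$roi_ids, modality = ref$modality, directed = ref$directed,
              weight_kind = "custom", roi_names = ref$roi_names)
}

#' Group robustness connectivity matrix
#'
#' Mean of the subjects' binary matrices: each entry is the fraction of
#' subjects in which the connection is present (0.1 means 10% of subjects
#' show it, 0.9 means 90%).
#'
#' @param stack a [subject_stack()] of binary matrices.
#' @return robustness-CM as a [conn_matrix()] with probability weights.
#' @export
robustness_cm <- function(stack) {
  for (m in stack$matrices)
    if (!is_binary_cm(m)) stop("robustness_cm requires binary matrices")
  vals <- Reduce(`+`, lapply(stack$matrices, `[[`, "values")) /
    length(stack$matrices)
  ref <- stack$matrices[[1]]
  conn_matrix(vals, ref$roi_ids, modality = ref$modality,
              directed = ref$directed, weight_kind = "probability",
              roi_names = ref$roi_names)
}

#' Combined connectivity matrix (mean masked by robustness)
#'
#' Implements `combined = mean * (robustness > tau)` with a strict
#' inequality: entries whose robustness is exactly `tau` are zeroed. With
#' the default `tau = 0.8`, surviving entries are nonzero in more than 80%
#' of subjects.
#'
#' @param mean_cm group mean [conn_matrix()].
#' @param robustness_cm group robustness [conn_matrix()].
#' @param tau robustness threshold in `[0, 1]` (default 0.8).
#' @return combined [conn_matrix()].
#' @export
combined_cm <- function(mean_cm, robustness_cm, tau = 0.8) {
  stopifnot_conn(mean_cm); stopifnot_conn(robustness_cm)
  check_same_rois(mean_cm, robustness_cm)
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  vals <- mean_cm$values * (robustness_cm$values > tau)
  conn_matrix(vals, mean_cm$roi_ids, modality = mean_cm$modality,
              directed = mean_cm$directed, weight_kind = mean_cm$weight_kind,
              roi_names = mean_cm$roi_names)
}

#' Hybrid structural-functional connectivity matrix
#'
#' Elementwise (Hadamard) product of the structural and functional matrices:
#' each sf entry weighs a functional correlation by the fiber count of the
#' same connection, preserving the per-connection meaning of the entries.
#'
#' @param s structural [conn_matrix()].
#' @param f functional [conn_matrix()] on the same ROI set/order.
#' @return sf-CM as a [conn_matrix()] with modality `"sf"`.
#' @export
hybrid_sf <- function(s, f) {
  stopifnot_conn(s); stopifnot_conn(f)
  check_same_rois(s, f)
  conn_matrix(s$values * f$values, s$roi_ids, modality = "sf",
              directed = s$directed || f$directed, weight_kind = "custom",
              roi_names = s$roi_names)
}

#' Direct / mediated decomposition of functional connections
#'
#' Splits the binary functional matrix into connections backed by a direct
#' structural ("axonal") edge and connections that are functionally
#' correlated without one: `direct = s AND f`, `mediated = f AND NOT s`.
#' The two parts partition the functional edge set: their union is `f_bin`
#' and their intersection is empty. Edges present only structurally appear
#' in neither part.
#'
#' @param s_bin binary structural [conn_matrix()].
#' @param f_bin binary functional [conn_matrix()] on the same ROI order.
#' @return list with binary [conn_matrix()] elements `direct` and
#'   `mediated`.
#' @export
decompose_direct_mediated <- function(s_bin, f_bin) {
  stopifnot_conn(s_bin); stopifnot_conn(f_bin)
  check_same_rois(s_bin, f_bin)
  if (!is_binary_cm(s_bin) || !is_binary_cm(f_bin))
    stop("decomposition requires binary matrices")
  direct <- s_bin$values * f_bin$values
  mediated <- f_bin$values * (1 - s_bin$values)
  list(direct = conn_matrix(direct, s_bin$roi_ids, modality = "sf",
                            weight_kind = "binary", roi_names = s_bin$roi_names),
       mediated = conn_matrix(mediated, s_bin$roi_ids, modality = "sf",
                              weight_kind = "binary",
                              roi_names = s_bin$roi_names))
}

#' Shortest mediated path through the structural graph
#'
#' Finds the path with the fewest intermediate regions between two ROIs in
#' the undirected graph of a binary structural matrix, by breadth-first
#' search. Ties are broken by canonical ROI order at each expansion, so the
#' result is deterministic. Optionally enumerates every minimum-length path.
#'
#' @param s_bin binary structural [conn_matrix()].
#' @param source,target ROI label ids or ROI names.
#' @param all_shortest if TRUE, return a list of all minimum-length paths.
#' @return character vector of ROI names along the path (including source
#'   and target), `NULL` when disconnected; or a list of such vectors when
#'   `all_shortest`.
#' @export
mediated_path <- function(s_bin, source, target, all_shortest = FALSE) {
  stopifnot_conn(s_bin)
  if (!is_binary_cm(s_bin)) stop("mediated_path requires a binary matrix")
  resolve <- function(x) {
    i <- match(as.character(x), s_bin$roi_names)
    if (is.na(i)) i <- match(suppressWarnings(as.integer(x)), s_bin$roi_ids)
    if (is.na(i)) stop("unknown ROI: ", x)
    i
  }
  src <- resolve(source); tgt <- resolve(target)
  if (src == tgt) stop("source and target must differ")
  A <- (s_bin$values + t(s_bin$values)) > 0
  R <- nrow(A)
  dist <- rep(NA_integer_, R); parent <- rep(NA_integer_, R)
  dist[src] <- 0L
  frontier <- src
  while (length(frontier) && is.na(dist[tgt])) {
    nxt <- integer(0)
    for (u in frontier) {                 # frontier kept in ascending order
      for (v in which(A[u, ])) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          parent[v] <- u                  # first (lowest-order) predecessor
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- sort(unique(nxt))
  }
  if (is.na(dist[tgt])) return(NULL)
  if (!all_shortest) {
    path <- tgt
    while (path[1] != src) path <- c(parent[path[1]], path)
    return(s_bin$roi_names[path])
  }
  # enumerate all minimum-length paths by DFS constrained to dist layers
  paths <- list()
  walk <- function(u, acc) {
    if (u == tgt) { paths[[length(paths) + 1]] <<- acc; return(invisible()) }
    for (v in which(A[u, ] & dist == dist[u] + 1L)) walk(v, c(acc, v))
  }
  walk(src, src)
  lapply(paths, function(p) s_bin$roi_names[p])
}
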