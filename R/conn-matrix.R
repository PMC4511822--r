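#' Connectivity matrix container
#'
#' A `conn_matrix` is a square ROI-by-ROI matrix tagged with the imaging
#' modality it derives from, whether it is directed, and the semantics of its
#' weights. It is the common currency passed between every stage of the
#' toolbox: per-subject matrices, group means, robustness maps and binary
#' masks are all `conn_matrix` objects sharing one canonical ROI ordering.
#'
#' @param values square numeric matrix; the diagonal must be zero.
#' @param roi_ids integer vector of parcellation label ids, one per row, in
#'   the order of `values`.
#' @param modality one of `"a"`, `"s"`, `"f"`, `"e"`, `"pet"`, `"sf"`,
#'   `"custom"` — anatomical, structural, functional, effective, PET
#'   uptake, hybrid structural-functional, or user-defined.
#' @param directed logical; undirected matrices must be symmetric.
#' @param weight_kind what an entry measures: `"count"` (streamlines),
#'   `"mean_length_mm"`, `"correlation"`, `"ratio"`, `"gc"` (Granger log
#'   variance ratio), `"binary"`, `"probability"` (robustness fraction), or
#'   `"custom"`.
#' @param roi_names optional character vector of ROI names (used for
#'   path reporting and plotting); defaults to the ids.
#' @return an object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, roi_ids, modality = "custom", directed = FALSE,
                        weight_kind = "custom", roi_names = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  roi_ids <- as.integer(roi_ids)
  if (length(roi_ids) != nrow(values)) stop("roi_ids length must match matrix dimension")
  if (anyDuplicated(roi_ids)) stop("roi_ids must be unique")
  modality <- match.arg(modality, c("a", "s", "f", "e", "pet", "sf", "custom"))
  weight_kind <- match.arg(weight_kind,
    c("count", "mean_length_mm", "orientation_vector", "correlation",
      "ratio", "gc", "binary", "probability", "custom"))
  if (any(!is.finite(values))) stop("connectivity matrix contains non-finite entries")
  if (any(abs(diag(values)) > 0)) stop("connectivity matrix diagonal must be zero")
  if (!directed && max(abs(values - t(values))) > 1e-8)
    stop("undirected connectivity matrix must be symmetric")
  if (weight_kind == "binary" && !all(values %in% c(0, 1)))
    stop("binary connectivity matrix may contain only 0 and 1")
  if (weight_kind == "correlation" && (min(values) < -1 - 1e-12 || max(values) > 1 + 1e-12))
    stop("correlation entries must lie in [-1, 1]")
  if (weight_kind == "probability" && (min(values) < 0 || max(values) > 1))
    stop("probability entries must lie in [0, 1]")
  if (is.null(roi_names)) roi_names <- as.character(roi_ids)
  dimnames(values) <- list(roi_names, roi_names)
  structure(
    list(values = values, roi_ids = roi_ids, modality = modality,
         directed = isTRUE(directed), weight_kind = weight_kind,
         roi_names = as.character(roi_names)),
    class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d x %d, modality=%s, %s, weights=%s\n",
              nrow(x$values), ncol(x$values), x$modality,
              if (x$directed) "directed" else "undirected", x$weight_kind))
  nz <- sum(x$values != 0)
  cat(sprintf("  nonzero entries: %d (%.1f%%)\n", nz,
              100 * nz / max(1, length(x$values) - nrow(x$values))))
  invisible(x)
}

#' @export
dim.conn_matrix <- function(x) dim(x$values)

n_rois <- function(cm) nrow(cm$values)

stopifnot_conn <- function(cm) {
  if (!inherits(cm, "conn_matrix")) stop("expected a conn_matrix object")
  invisible(cm)
}

check_same_rois <- function(a, b) {
  if (!identical(a$roi_ids, b$roi_ids))
    stop("connectivity matrices do not share the same ROI set/order")
  invisible(NULL)
}

is_binary_cm <- function(cm) all(cm$values %in% c(0, 1))

#' Write a connectivity matrix to its text container
#'
#' The on-disk format is a commented key:value header (modality, directedness,
#' weight kind, ROI ids and names) followed by the dense tab-separated matrix
#' body. The round trip is lossless.
#'
#' @param cm a [conn_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(cm, path) {
  stopifnot_conn(cm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#conn_matrix v1",
    paste0("#modality: ", cm$modality),
    paste0("#directed: ", cm$directed),
    paste0("#weight_kind: ", cm$weight_kind),
    paste0("#roi_ids: ", paste(cm$roi_ids, collapse = "\t")),
    paste0("#roi_names: ", paste(cm$roi_names, collapse = "\t"))
  ), con)
  utils::write.table(format(cm$values, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a connectivity matrix from its text container
#'
#' @param path file written by [write_matrix()].
#' @return a [conn_matrix()].
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || hdr[1] != "#conn_matrix v1")
    stop("not a conn_matrix container: ", path)
  field <- function(key) {
    ln <- grep(paste0("^#", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("missing header field '", key, "' in ", path)
    sub(paste0("^#", key, ": "), "", ln[1])
  }
  roi_ids <- as.integer(strsplit(field("roi_ids"), "\t")[[1]])
  roi_names <- strsplit(field("roi_names"), "\t")[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  vals <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  if (nrow(vals) != length(roi_ids) || ncol(vals) != length(roi_ids))
    stop(sprintf("matrix body is %dx%d but header lists %d ROIs",
                 nrow(vals), ncol(vals), length(roi_ids)))
  conn_matrix(vals, roi_ids, modality = field("modality"),
              directed = as.logical(field("directed")),
              weight_kind = field("weight_kind"), roi_names = roi_names)
}
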