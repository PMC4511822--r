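#' ROI signal set (BOLD time series or PET time-activity curves)
#'
#' An ROI x time matrix with sampling metadata. Row order follows the
#' canonical ROI ordering of the parcellation the signals were extracted
#' from.
#'
#' @param values ROI x T numeric matrix.
#' @param roi_ids ordered label ids, one per row.
#' @param sampling repetition time (seconds, scalar) for BOLD, or a vector of
#'   frame durations for PET.
#' @param modality `"bold"` or `"pet"`.
#' @param roi_names optional ROI names.
#' @return object of class `roi_signals`.
#' @export
roi_signals <- function(values, roi_ids, sampling = 1, modality = c("bold", "pet"),
                        roi_names = NULL) {
  values <- as.matrix(values)
  modality <- match.arg(modality)
  roi_ids <- as.integer(roi_ids)
  if (nrow(values) != length(roi_ids)) stop("one row per ROI required")
  if (ncol(values) < 2) stop("signal set needs at least 2 time samples")
  if (any(!is.finite(values))) stop("signal set contains non-finite values")
  if (is.null(roi_names)) roi_names <- as.character(roi_ids)
  rownames(values) <- roi_names
  structure(list(values = values, roi_ids = roi_ids, sampling = sampling,
                 modality = modality, roi_names = as.character(roi_names)),
            class = "roi_signals")
}

#' @export
print.roi_signals <- function(x, ...) {
  cat(sprintf("<roi_signals> %d ROIs x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$modality))
  invisible(x)
}

#' Write / read ROI signals as TSV
#'
#' Header comments carry modality and sampling; the body is one row per ROI
#' (`label_id`, `name`, then one column per time sample).
#'
#' @param sig a [roi_signals()].
#' @param path file path.
#' @return `path` / a [roi_signals()].
#' @export
write_signals <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#modality: ", sig$modality),
               paste0("#sampling: ", paste(sig$sampling, collapse = "\t"))), con)
  df <- data.frame(label_id = sig$roi_ids, name = sig$roi_names,
                   sig$values, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("t", seq_len(ncol(sig$values)))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  lines <- readLines(path, n = 10)
  modality <- sub("^#modality: ", "", grep("^#modality:", lines, value = TRUE)[1])
  sampling <- as.numeric(strsplit(
    sub("^#sampling: ", "", grep("^#sampling:", lines, value = TRUE)[1]), "\t")[[1]])
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  roi_signals(as.matrix(df[, -(1:2), drop = FALSE]), df$label_id,
              sampling = sampling, modality = modality, roi_names = df$name)
}

#' Write / read a per-ROI morphometry table as TSV
#'
#' One row per ROI; cortical rows carry CT (mm), SA (mm^2) and GMV (mm^3),
#' subcortical rows carry volume (mm^3); FA and MD columns apply to all
#' ROIs. Inapplicable cells are NA.
#'
#' @param morph data.frame with `label_id`, `name`, `tissue_class` and
#'   measure columns.
#' @param path file path.
#' @return `path` / the data.frame.
#' @export
write_morphometry <- function(morph, path) {
  utils::write.table(morph, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_morphometry
#' @export
read_morphometry <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
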