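#' Parcellation of a brain volume into labelled regions of interest
#'
#' Couples a 3D integer label volume (0 = background) with its voxel-to-mm
#' affine and an ROI table giving, for every label, a name, a hemisphere and
#' a cortical/subcortical tissue class. The ROI table is always stored in the
#' canonical ordering used by every matrix in the toolbox: block I holds the
#' subcortical regions with left/right homologues interleaved, block II the
#' left cortical regions, block III the right cortical regions; within each
#' block rows sort alphabetically by ROI name.
#'
#' @param labels 3D integer array of parcellation labels.
#' @param affine 4x4 voxel-to-mm transform (0-based voxel indices).
#' @param roi_table data.frame with columns `label_id`, `name`, `hemisphere`
#'   (`left`/`right`/`none`) and `tissue_class` (`cortical`/`subcortical`).
#' @return an object of class `parcellation`.
#' @export
parcellation <- function(labels, affine = diag(4), roi_table) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3) stop("label volume must be 3D")
  storage.mode(labels) <- "integer"
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be a 4x4 matrix")
  need <- c("label_id", "name", "hemisphere", "tissue_class")
  if (!all(need %in% names(roi_table)))
    stop("roi_table must have columns: ", paste(need, collapse = ", "))
  roi_table <- as.data.frame(roi_table, stringsAsFactors = FALSE)
  roi_table$label_id <- as.integer(roi_table$label_id)
  if (any(roi_table$label_id <= 0)) stop("label ids must be positive")
  if (anyDuplicated(roi_table$label_id)) stop("label ids must be unique")
  if (!all(roi_table$hemisphere %in% c("left", "right", "none")))
    stop("hemisphere must be left, right or none")
  if (!all(roi_table$tissue_class %in% c("cortical", "subcortical")))
    stop("tissue_class must be cortical or subcortical")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  orphan <- setdiff(present, roi_table$label_id)
  if (length(orphan))
    stop("labels present in volume but missing from table: ",
         paste(orphan, collapse = ", "))
  roi_table <- roi_table[canonical_roi_order(roi_table), , drop = FALSE]
  rownames(roi_table) <- NULL
  structure(list(labels = labels, affine = affine, roi_table = roi_table),
            class = "parcellation")
}

#' Canonical ROI ordering
#'
#' Returns the permutation that sorts an ROI table into the block scheme used
#' throughout: I subcortical (left/right interleaved, name-major), II left
#' cortical, III right cortical; alphabetical by name within block. The
#' ordering depends only on table content, never on file order.
#'
#' @param roi_table data.frame with `name`, `hemisphere`, `tissue_class`.
#' @return integer permutation of `seq_len(nrow(roi_table))`.
#' @export
canonical_roi_order <- function(roi_table) {
  block <- ifelse(roi_table$tissue_class == "subcortical", 1L,
                  ifelse(roi_table$hemisphere == "right", 3L, 2L))
  hemi_rank <- match(roi_table$hemisphere, c("left", "right", "none"))
  # within the subcortical block homologous L/R pairs sit adjacent (name-major)
  order(block, roi_table$name, hemi_rank)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %s volume, %d ROIs (%d subcortical, %d cortical)\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$roi_table),
              sum(x$roi_table$tissue_class == "subcortical"),
              sum(x$roi_table$tissue_class == "cortical")))
  invisible(x)
}

roi_ids_of <- function(parc) parc$roi_table$label_id
roi_names_of <- function(parc) parc$roi_table$name

#' Read a parcellation label volume and its label table
#'
#' The volume must be a 3D integer NIfTI image; the companion label table is
#' a 4-column TSV (`label_id`, `name`, `hemisphere`, `tissue_class`), either
#' passed explicitly or resolved by the `<stem>_labels.tsv` naming
#' convention next to the volume. The returned ROI table is restricted to
#' labels actually present in the volume.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param label_table_path optional TSV path; default derives from `path`.
#' @return a [parcellation()].
#' @export
read_label_volume <- function(path, label_table_path = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop("parcellation volume must be 3D: ", path)
  if (max(abs(arr - round(arr))) > 0)
    stop("parcellation volume has non-integer voxel data: ", path)
  arr <- array(as.integer(round(arr)), dim = dim(arr))
  if (all(arr == 0L)) stop("no ROIs: label volume is all zero")
  if (is.null(label_table_path)) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    label_table_path <- paste0(stem, "_labels.tsv")
  }
  if (!file.exists(label_table_path))
    stop("label table not found: ", label_table_path)
  tab <- utils::read.delim(label_table_path, stringsAsFactors = FALSE)
  present <- setdiff(sort(unique(as.vector(arr))), 0L)
  orphan <- setdiff(present, tab$label_id)
  if (length(orphan))
    stop("labels in volume missing from label table: ",
         paste(orphan, collapse = ", "))
  tab <- tab[tab$label_id %in% present, , drop = FALSE]
  aff <- tryCatch(RNifti::xform(img), error = function(e) diag(4))
  parcellation(arr, aff, tab)
}

#' Write a parcellation to NIfTI plus label-table TSV
#'
#' @param parc a [parcellation()].
#' @param path output NIfTI path; the table lands at `<stem>_labels.tsv`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(parc, path) {
  img <- RNifti::asNifti(parc$labels)
  RNifti::writeNifti(img, path, datatype = "int32")
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  utils::write.table(parc$roi_table, paste0(stem, "_labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map mm-space points to parcellation labels
#'
#' Points transform through the inverse affine and floor to 0-based voxel
#' indices; out-of-volume points map to label 0 (background).
#'
#' @param parc a [parcellation()].
#' @param points n x 3 matrix of mm coordinates.
#' @return integer vector of labels (0 = background / outside).
#' @export
labels_at_points <- function(parc, points) {
  points <- matrix(points, ncol = 3)
  inv <- solve(parc$affine)
  vox <- cbind(points, 1) %*% t(inv)
  idx <- floor(vox[, 1:3, drop = FALSE])
  d <- dim(parc$labels)
  inside <- idx[, 1] >= 0 & idx[, 1] < d[1] &
            idx[, 2] >= 0 & idx[, 2] < d[2] &
            idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- integer(nrow(points))
  if (any(inside)) {
    flat <- idx[inside, 1] + d[1] * (idx[inside, 2] + d[2] * idx[inside, 3]) + 1
    out[inside] <- parc$labels[flat]
  }
  out
}

#' ROI centroids in mm
#'
#' @param parc a [parcellation()].
#' @return matrix (ROI x 3) of mean labelled-voxel center coordinates in mm,
#'   rows in canonical order.
#' @export
roi_centroids <- function(parc) {
  d <- dim(parc$labels)
  ids <- roi_ids_of(parc)
  out <- matrix(NA_real_, length(ids), 3,
                dimnames = list(parc$roi_table$name, c("x", "y", "z")))
  lin <- which(parc$labels != 0L)
  lab <- parc$labels[lin]
  i <- (lin - 1) %% d[1]
  j <- ((lin - 1) %/% d[1]) %% d[2]
  k <- (lin - 1) %/% (d[1] * d[2])
  vox <- cbind(i + 0.5, j + 0.5, k + 0.5, 1)  # voxel centers
  mm <- vox %*% t(parc$affine)
  for (r in seq_along(ids)) {
    sel <- lab == ids[r]
    out[r, ] <- colMeans(mm[sel, 1:3, drop = FALSE])
  }
  out
}
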