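#' Assign streamlines to ROI pairs by their endpoints
#'
#' Each streamline endpoint maps to the parcellation label of its containing
#' voxel (mm to voxel through the inverse affine, floored to a 0-based
#' index); endpoints outside the volume or in background yield no label. A
#' streamline is assigned when both endpoints carry a nonzero label. The
#' arc length is the sum of segment lengths; the unit direction is the
#' end-to-end vector normalized and sign-flipped so its first nonzero
#' component is positive.
#'
#' @param tract a [tractogram()].
#' @param parc a [parcellation()] sharing the tractogram's frame.
#' @return data.frame with one row per streamline: `roi_start`, `roi_end`
#'   (NA where unlabelled), `length_mm`, `dx`, `dy`, `dz`, `assigned`.
#' @export
assign_streamlines <- function(tract, parc) {
  n <- length(tract$streamlines)
  starts <- t(vapply(tract$streamlines, function(s) s[1, ], numeric(3)))
  ends <- t(vapply(tract$streamlines, function(s) s[nrow(s), ], numeric(3)))
  lab_s <- labels_at_points(parc, starts)
  lab_e <- labels_at_points(parc, ends)
  lens <- vapply(tract$streamlines, function(s) {
    seg <- diff(s)
    sum(sqrt(rowSums(seg^2)))
  }, 0)
  dirs <- ends - starts
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs / ifelse(nrm > 0, nrm, 1)
  for (i in seq_len(n)) {              # sign convention: first nonzero > 0
    nz <- which(abs(dirs[i, ]) > 1e-12)
    if (length(nz) && dirs[i, nz[1]] < 0) dirs[i, ] <- -dirs[i, ]
  }
  data.frame(roi_start = ifelse(lab_s == 0, NA_integer_, lab_s),
             roi_end = ifelse(lab_e == 0, NA_integer_, lab_e),
             length_mm = lens, dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
             assigned = lab_s != 0 & lab_e != 0)
}

#' Structural connectivity matrices from streamline assignments
#'
#' Tallies assigned streamlines into the fiber-count matrix (s-CM), the mean
#' fiber length matrix, and the mean fiber orientation per pair (normalized
#' mean of the sign-aligned end-to-end unit vectors). Streamlines with both
#' endpoints in one ROI ("loops") are excluded from the matrices and counted
#' in the QC summary.
#'
#' @param assignments output of [assign_streamlines()].
#' @param parc a [parcellation()] fixing the ROI set and order.
#' @return list with `count` (s-CM, a [conn_matrix()]), `length`
#'   (mean mm, [conn_matrix()]), `orientation` (R x R x 3 array of mean unit
#'   vectors; zero where no fibers) and `qc` (assigned / orphan / loop
#'   counts).
#' @export
structural_cm <- function(assignments, parc) {
  ids <- roi_ids_of(parc)
  R <- length(ids)
  cnt <- len <- matrix(0, R, R)
  ori <- array(0, dim = c(R, R, 3))
  loops <- 0L
  a <- assignments[assignments$assigned, , drop = FALSE]
  for (r in seq_len(nrow(a))) {
    i <- match(a$roi_start[r], ids); j <- match(a$roi_end[r], ids)
    if (is.na(i) || is.na(j)) next
    if (i == j) { loops <- loops + 1L; next }
    cnt[i, j] <- cnt[i, j] + 1
    len[i, j] <- len[i, j] + a$length_mm[r]
    ori[i, j, ] <- ori[i, j, ] + c(a$dx[r], a$dy[r], a$dz[r])
  }
  cnt <- cnt + t(cnt)
  len <- len + t(len)
  for (k in 1:3) ori[, , k] <- ori[, , k] + t(ori[, , k])
  mean_len <- ifelse(cnt > 0, len / cnt, 0)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    v <- ori[i, j, ]
    nv <- sqrt(sum(v^2))
    ori[i, j, ] <- if (nv > 0) v / nv else c(0, 0, 0)
  }
  nms <- roi_names_of(parc)
  list(
    count = conn_matrix(cnt, ids, modality = "s", weight_kind = "count",
                        roi_names = nms),
    length = conn_matrix(mean_len, ids, modality = "s",
                         weight_kind = "mean_length_mm", roi_names = nms),
    orientation = ori,
    qc = list(n_assigned = sum(assignments$assigned) - loops,
              n_orphan = sum(!assignments$assigned), n_loop = loops))
}

#' Per-ROI means of a scalar map (FA, MD)
#'
#' Accepts either a 3D scalar volume on the parcellation grid (means over the
#' labelled voxels) or a complete per-ROI table (columns `label_id` and the
#' measure), which is validated and passed through.
#'
#' @param scalar 3D numeric array or data.frame.
#' @param parc a [parcellation()].
#' @param measure column name when `scalar` is a table.
#' @return named numeric vector of per-ROI means in canonical order.
#' @export
roi_scalar_means <- function(scalar, parc, measure = "FA") {
  ids <- roi_ids_of(parc)
  if (is.data.frame(scalar)) {
    miss <- setdiff(ids, scalar$label_id)
    if (length(miss)) stop("table missing ROIs: ", paste(miss, collapse = ", "))
    out <- scalar[[measure]][match(ids, scalar$label_id)]
  } else {
    scalar <- as.array(scalar)
    if (!identical(dim(scalar), dim(parc$labels)))
      stop("scalar volume grid does not match parcellation grid")
    lab <- as.vector(parc$labels)
    keep <- lab != 0L
    sums <- rowsum(as.vector(scalar)[keep], lab[keep])
    cts <- rowsum(rep(1, sum(keep)), lab[keep])
    out <- (sums / cts)[match(ids, as.integer(rownames(sums))), 1]
  }
  stats::setNames(out, roi_names_of(parc))
}
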