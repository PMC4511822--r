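#' Extract ROI-mean time series from a 4D volume
#'
#' For each ROI and time point, the spatial mean over the ROI's voxels.
#'
#' @param series_4d 4D numeric array (x, y, z, t) on the parcellation grid.
#' @param parc a [parcellation()].
#' @param sampling repetition time (s) or frame durations.
#' @param modality `"bold"` or `"pet"`.
#' @return a [roi_signals()] in canonical ROI order.
#' @export
extract_roi_timeseries <- function(series_4d, parc, sampling = 1,
                                   modality = "bold") {
  series_4d <- as.array(series_4d)
  if (length(dim(series_4d)) != 4) stop("expected a 4D series")
  if (!identical(dim(series_4d)[1:3], dim(parc$labels)))
    stop("4D grid does not match parcellation grid")
  Tn <- dim(series_4d)[4]
  lab <- as.vector(parc$labels)
  keep <- lab != 0L
  mat <- matrix(series_4d, ncol = Tn)[keep, , drop = FALSE]
  sums <- rowsum(mat, lab[keep])
  cts <- as.vector(rowsum(rep(1, sum(keep)), lab[keep]))
  means <- sums / cts
  ids <- roi_ids_of(parc)
  roi_signals(means[match(ids, as.integer(rownames(sums))), , drop = FALSE],
              ids, sampling = sampling, modality = modality,
              roi_names = roi_names_of(parc))
}

#' Pairwise Pearson correlation of ROI signals
#'
#' Correlates every ROI pair's series across time and attaches two-sided
#' p-values from the t transform with T - 2 degrees of freedom.
#'
#' @param signals a [roi_signals()] with T >= 3 and no constant series.
#' @return object of class `corr_result`: list with `r` (a [conn_matrix()]
#'   of correlations, zero diagonal), `p` (symmetric p-value matrix, unit
#'   diagonal) and `n_samples`.
#' @export
pearson_fc <- function(signals) {
  x <- signals$values
  Tn <- ncol(x)
  if (Tn < 3) stop("need at least 3 time samples")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance series for ROI(s): ",
         paste(signals$roi_names[sds == 0], collapse = ", "))
  r <- stats::cor(t(x))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((Tn - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = Tn - 2)
  diag(r) <- 0
  diag(p) <- 1
  modality <- if (identical(signals$modality, "pet")) "pet" else "f"
  structure(list(
    r = conn_matrix(r, signals$roi_ids, modality = modality,
                    weight_kind = "correlation", roi_names = signals$roi_names),
    p = p, n_samples = Tn), class = "corr_result")
}

#' PET connectivity matrix from time-activity curves
#'
#' Pearson correlation across frames of the per-ROI TACs, with the same
#' p-value machinery as the BOLD path. With few frames (the typical dynamic
#' acquisition has 8) the t test runs on very few degrees of freedom; a
#' warning flags that regime.
#'
#' @param tacs a [roi_signals()] with modality `"pet"`.
#' @return a `corr_result` (see [pearson_fc()]).
#' @export
pet_cm <- function(tacs) {
  if (ncol(tacs$values) < 3) stop("need at least 3 frames")
  if (ncol(tacs$values) <= 8)
    warning("only ", ncol(tacs$values),
            " frames: correlation p-values have ", ncol(tacs$values) - 2,
            " degrees of freedom", call. = FALSE)
  tacs$modality <- "pet"
  pearson_fc(tacs)
}

#' Bonferroni threshold of a correlation matrix
#'
#' The family is the set of unique off-diagonal pairs, R(R-1)/2; an edge
#' survives when its p-value is below `alpha` divided by the family size.
#'
#' @param result a `corr_result` from [pearson_fc()] or [pet_cm()].
#' @param alpha significance level (default 0.05).
#' @return list with `binary` (surviving edges as a binary [conn_matrix()]),
#'   `weighted` (correlations masked by `binary`) and `alpha_effective`.
#' @export
threshold_bonferroni <- function(result, alpha = 0.05) {
  if (!inherits(result, "corr_result")) stop("expected a corr_result")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  R <- n_rois(result$r)
  if (R < 2) stop("need at least 2 ROIs")
  alpha_eff <- alpha / (R * (R - 1) / 2)
  bin <- (result$p < alpha_eff) * 1
  diag(bin) <- 0
  wt <- result$r$values * bin
  list(binary = conn_matrix(bin, result$r$roi_ids, modality = result$r$modality,
                            weight_kind = "binary", roi_names = result$r$roi_names),
       weighted = conn_matrix(wt, result$r$roi_ids, modality = result$r$modality,
                              weight_kind = "correlation",
                              roi_names = result$r$roi_names),
       alpha_effective = alpha_eff)
}

#' Sum dynamic PET frames into a 3D volume
#'
#' @param pet_4d 4D array (x, y, z, frame).
#' @param frame_durations optional frame durations (unused by the plain sum;
#'   accepted for provenance).
#' @return 3D array of voxelwise frame sums.
#' @export
sum_pet_frames <- function(pet_4d, frame_durations = NULL) {
  pet_4d <- as.array(pet_4d)
  if (length(dim(pet_4d)) == 3) return(pet_4d)
  if (length(dim(pet_4d)) != 4) stop("expected a 3D or 4D PET volume")
  apply(pet_4d, 1:3, sum)
}

#' Regional SUV and reference-relative SUV
#'
#' SUV is the ROI mean of the summed PET volume, optionally scaled by
#' dose/body-weight factors; rSUV divides by the SUV of a reference region
#' (classically the cerebellum).
#'
#' @param summed_volume 3D array from [sum_pet_frames()].
#' @param parc a [parcellation()].
#' @param reference_roi label id of the reference region.
#' @param scale optional scalar (e.g. body weight / injected dose).
#' @return data.frame with `label_id`, `name`, `SUV`, `rSUV`.
#' @export
roi_suv <- function(summed_volume, parc, reference_roi, scale = 1) {
  means <- roi_scalar_means(summed_volume, parc, measure = NULL)
  ids <- roi_ids_of(parc)
  if (!reference_roi %in% ids) stop("reference ROI ", reference_roi, " not in parcellation")
  suv <- means * scale
  ref <- suv[match(reference_roi, ids)]
  if (!is.finite(ref) || ref == 0) stop("reference ROI has zero mean uptake")
  data.frame(label_id = ids, name = roi_names_of(parc),
             SUV = as.numeric(suv), rSUV = as.numeric(suv / ref))
}

#' SUV table from ROI TACs
#'
#' Table-input counterpart of [roi_suv()]: SUV is the frame sum of each
#' ROI's TAC (durations applied when given), rSUV relative to the reference.
#'
#' @param tacs a [roi_signals()] with modality `"pet"`.
#' @param reference_roi label id of the reference region.
#' @return data.frame with `label_id`, `name`, `SUV`, `rSUV`.
#' @export
roi_suv_from_tacs <- function(tacs, reference_roi) {
  w <- if (length(tacs$sampling) == ncol(tacs$values)) tacs$sampling
       else rep(1, ncol(tacs$values))
  suv <- as.numeric(tacs$values %*% w)
  i <- match(reference_roi, tacs$roi_ids)
  if (is.na(i)) stop("reference ROI ", reference_roi, " not in signal set")
  if (suv[i] == 0) stop("reference ROI has zero mean uptake")
  data.frame(label_id = tacs$roi_ids, name = tacs$roi_names,
             SUV = suv, rSUV = suv / suv[i])
}
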