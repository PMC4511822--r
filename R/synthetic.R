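# Synthetic study generators with planted ground truth. Every generator is a
# pure function of its arguments including the seed.

local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

#' Toy parcellation of mirrored boxes
#'
#' Builds a label volume of disjoint axis-aligned 2x2x2-voxel boxes, one per
#' ROI, mirrored left/right across the mid-sagittal plane so hemispheric
#' symmetry properties are exercisable. Roughly a quarter of the ROI pairs
#' are marked subcortical, the rest cortical. The affine is the identity,
#' so mm coordinates coincide with (0-based) voxel indices.
#'
#' @param n_rois even number of ROIs (>= 2); half per hemisphere.
#' @param shape 3-vector of volume dimensions.
#' @param seed RNG seed (kept for API symmetry; the construction is
#'   deterministic).
#' @return a [parcellation()].
#' @export
make_toy_parcellation <- function(n_rois, shape = c(24, 24, 24), seed = 1) {
  if (n_rois < 2) stop("need at least 2 ROIs")
  if (n_rois %% 2 != 0) stop("n_rois must be even (hemisphere pairing)")
  n_pairs <- n_rois / 2
  half <- floor(shape[1] / 2)
  ax <- seq(1, half - 2, by = 4)
  ay <- seq(1, shape[2] - 3, by = 4)
  az <- seq(1, shape[3] - 3, by = 4)
  cells <- expand.grid(x = ax, y = ay, z = az)
  if (nrow(cells) < n_pairs)
    stop("boxes cannot fit: shape supports only ", nrow(cells), " ROI pairs")
  labels <- array(0L, dim = shape)
  n_sub <- max(1L, ceiling(n_pairs / 4))
  rows <- vector("list", n_rois)
  for (p in seq_len(n_pairs)) {
    cx <- cells$x[p]; cy <- cells$y[p]; cz <- cells$z[p]
    idl <- 2L * p - 1L; idr <- 2L * p
    labels[cx + (1:2), cy + (1:2), cz + (1:2)] <- idl
    mx <- shape[1] + 1 - (cx + (1:2))  # mirrored x indices (1-based)
    labels[mx, cy + (1:2), cz + (1:2)] <- idr
    cls <- if (p <= n_sub) "subcortical" else "cortical"
    base <- if (cls == "subcortical") sprintf("subc%02d", p) else sprintf("cort%02d", p)
    rows[[2 * p - 1]] <- data.frame(label_id = idl, name = base,
                                    hemisphere = "left", tissue_class = cls)
    rows[[2 * p]] <- data.frame(label_id = idr, name = base,
                                hemisphere = "right", tissue_class = cls)
  }
  roi_table <- do.call(rbind, rows)
  # homologous pairs share a base name; disambiguate with hemisphere suffix
  roi_table$name <- paste0(roi_table$name, "_",
                           ifelse(roi_table$hemisphere == "left", "L", "R"))
  parcellation(labels, diag(4), roi_table)
}

#' Streamlines with planted ROI-pair fiber counts
#'
#' For every pair (A, B) with count k, generates exactly k polylines whose
#' first point lies inside an A-labelled voxel and last point inside a
#' B-labelled voxel; interior points are arbitrary. Optionally adds orphan
#' streamlines with at least one endpoint in background.
#'
#' @param parc a [parcellation()].
#' @param pair_counts data.frame with columns `roi_a`, `roi_b`, `count`
#'   (unordered ROI pairs).
#' @param n_orphans number of unassignable streamlines to add.
#' @param seed RNG seed.
#' @return a [tractogram()] in the parcellation's mm frame.
#' @export
make_streamlines <- function(parc, pair_counts, n_orphans = 0, seed = 1) {
  local_seed(seed)
  ids <- roi_ids_of(parc)
  if (nrow(pair_counts) && !all(c(pair_counts$roi_a, pair_counts$roi_b) %in% ids))
    stop("pair_counts refers to ROI ids absent from the parcellation")
  d <- dim(parc$labels)
  vox_of <- function(lab) {
    lin <- which(parc$labels == lab)
    l <- lin[sample.int(length(lin), 1)] - 1
    c(l %% d[1], (l %/% d[1]) %% d[2], l %/% (d[1] * d[2]))
  }
  pt_in_vox <- function(v) v + 0.01 + stats::runif(3) * 0.98
  to_mm <- function(p) as.numeric((parc$affine %*% c(p, 1))[1:3])
  rand_interior <- function() to_mm(stats::runif(3) * (d - 1))
  sl <- list()
  if (nrow(pair_counts)) for (r in seq_len(nrow(pair_counts))) {
    for (k in seq_len(pair_counts$count[r])) {
      a <- to_mm(pt_in_vox(vox_of(pair_counts$roi_a[r])))
      b <- to_mm(pt_in_vox(vox_of(pair_counts$roi_b[r])))
      n_int <- sample(1:3, 1)
      mids <- t(replicate(n_int, rand_interior()))
      sl[[length(sl) + 1]] <- rbind(a, mids, b)
    }
  }
  if (n_orphans > 0) {
    bg <- which(parc$labels == 0L)
    for (k in seq_len(n_orphans)) {
      l <- bg[sample.int(length(bg), 1)] - 1
      v <- c(l %% d[1], (l %/% d[1]) %% d[2], l %/% (d[1] * d[2]))
      a <- to_mm(pt_in_vox(v))
      sl[[length(sl) + 1]] <- rbind(a, rand_interior())
    }
  }
  tractogram(sl, space_id = "toy")
}

#' Stationary first-order vector-autoregressive ROI time series
#'
#' Simulates `X_t = coupling %*% X_{t-1} + eps_t` with iid Gaussian
#' innovations, discarding a burn-in, as a fixture for functional and
#' effective (Granger) connectivity. Entry `coupling[j, i]` is the lag-1
#' influence of ROI i on ROI j.
#'
#' @param n_rois number of series.
#' @param T number of retained samples (>= 10).
#' @param coupling lag-1 coupling matrix (default zero); spectral radius
#'   must be < 1 for stationarity.
#' @param noise_sd innovation standard deviation.
#' @param seed RNG seed.
#' @param burn burn-in samples discarded (default 100).
#' @return a [roi_signals()] with modality `"bold"`.
#' @export
make_var_timeseries <- function(n_rois, T, coupling = NULL, noise_sd = 1,
                                seed = 1, burn = 100) {
  if (T < 10) stop("T must be >= 10")
  if (is.null(coupling)) coupling <- matrix(0, n_rois, n_rois)
  coupling <- as.matrix(coupling)
  if (max(Mod(eigen(coupling, only.values = TRUE)$values)) >= 1)
    stop("non-stationary coupling: spectral radius >= 1")
  local_seed(seed)
  total <- T + burn
  x <- matrix(0, n_rois, total)
  eps <- matrix(stats::rnorm(n_rois * total, sd = noise_sd), n_rois, total)
  x[, 1] <- eps[, 1]
  for (t in 2:total) x[, t] <- coupling %*% x[, t - 1] + eps[, t]
  roi_signals(x[, (burn + 1):total, drop = FALSE], seq_len(n_rois),
              sampling = 2, modality = "bold")
}

#' Two-group morphometry tables with planted effects
#'
#' Cortical ROIs receive CT/SA/GMV, subcortical ROIs a volume; all ROIs get
#' FA and MD. Group 2 means are shifted by `group_effects`; per-subject
#' Gaussian noise is added and values clamped to their physical ranges.
#'
#' @param parc a [parcellation()].
#' @param n_per_group integer pair (n1, n2), each >= 2.
#' @param baseline named list of baseline means (defaults: CT 2.5 mm,
#'   SA 1200 mm^2, GMV 3000 mm^3, volume 1500 mm^3, FA 0.45,
#'   MD 8e-4 mm^2/s).
#' @param group_effects named list measure -> scalar shift (all ROIs) or
#'   numeric vector named by label id (selected ROIs), added to group 2.
#' @param noise_sd named list of per-measure noise SDs (defaults scale with
#'   the baselines).
#' @param seed RNG seed.
#' @return list with `tables` (one morphometry data.frame per subject) and
#'   `group` (integer vector of 1/2).
#' @export
make_group_morphometry <- function(parc, n_per_group = c(15, 20),
                                   baseline = list(), group_effects = list(),
                                   noise_sd = list(), seed = 1) {
  if (any(n_per_group < 2)) stop("each group needs at least 2 subjects")
  base <- utils::modifyList(list(CT = 2.5, SA = 1200, GMV = 3000,
                                 volume = 1500, FA = 0.45, MD = 8e-4), baseline)
  if (any(unlist(base) <= 0)) stop("baseline measures must be positive")
  nsd <- utils::modifyList(list(CT = 0.2, SA = 100, GMV = 250,
                                volume = 120, FA = 0.04, MD = 5e-5), noise_sd)
  local_seed(seed)
  rt <- parc$roi_table
  cortical <- rt$tissue_class == "cortical"
  measures <- c("CT", "SA", "GMV", "volume", "FA", "MD")
  applies <- list(CT = cortical, SA = cortical, GMV = cortical,
                  volume = !cortical, FA = rep(TRUE, nrow(rt)),
                  MD = rep(TRUE, nrow(rt)))
  group <- rep(1:2, n_per_group)
  tables <- vector("list", sum(n_per_group))
  for (s in seq_along(group)) {
    df <- data.frame(label_id = rt$label_id, name = rt$name,
                     tissue_class = rt$tissue_class)
    for (m in measures) {
      v <- rep(NA_real_, nrow(rt))
      mu <- rep(base[[m]], nrow(rt))
      if (group[s] == 2 && !is.null(group_effects[[m]])) {
        ef <- group_effects[[m]]
        if (is.null(names(ef))) mu <- mu + ef
        else {
          hit <- match(names(ef), as.character(rt$label_id))
          mu[hit[!is.na(hit)]] <- mu[hit[!is.na(hit)]] + ef[!is.na(hit)]
        }
      }
      v[applies[[m]]] <- mu[applies[[m]]] +
        stats::rnorm(sum(applies[[m]]), sd = nsd[[m]])
      v <- pmax(v, 1e-6)
      if (m == "FA") v <- pmin(v, 0.999)
      df[[m]] <- v
    }
    tables[[s]] <- df
  }
  list(tables = tables, group = group)
}

#' PET time-activity curves with planted kinetic profiles
#'
#' Each ROI is assigned a smooth gamma-variate-like uptake profile; Gaussian
#' noise is added per frame. Defaults mirror an 8-frame dynamic acquisition.
#'
#' @param parc a [parcellation()].
#' @param n_frames number of frames (>= 2; default 8).
#' @param kinetic_profiles optional matrix (n_profiles x n_frames); ROIs are
#'   assigned profiles round-robin. Default: three gamma-variate curves with
#'   distinct washout constants.
#' @param noise_sd frame noise SD.
#' @param seed RNG seed.
#' @return a [roi_signals()] with modality `"pet"`.
#' @export
make_pet_tacs <- function(parc, n_frames = 8, kinetic_profiles = NULL,
                          noise_sd = 0.05, seed = 1) {
  if (n_frames < 2) stop("need at least 2 frames")
  tt <- seq_len(n_frames)
  if (is.null(kinetic_profiles)) {
    kinetic_profiles <- rbind(10 * tt^2 * exp(-tt / 1.5),
                              10 * tt^2 * exp(-tt / 3),
                              10 * tt * exp(-tt / 5))
  }
  local_seed(seed)
  ids <- roi_ids_of(parc)
  prof_idx <- ((seq_along(ids) - 1) %% nrow(kinetic_profiles)) + 1
  vals <- kinetic_profiles[prof_idx, , drop = FALSE] +
    matrix(stats::rnorm(length(ids) * n_frames, sd = noise_sd),
           length(ids), n_frames)
  roi_signals(vals, ids, sampling = rep(225, n_frames), modality = "pet",
              roi_names = roi_names_of(parc))
}

#' Write a complete synthetic study tree
#'
#' Emits a Study-Subject-Acquisition layout with one run per modality per
#' subject (morphometry TSV, TrackVis tractogram, BOLD ROI table, PET TAC
#' table), a shared parcellation at the study root, a participants table with
#' age/sex/group covariates, and a `truth.json` manifest recording every
#' planted quantity so tests never re-derive them.
#'
#' @param root output directory (created).
#' @param n_rois ROIs in the toy parcellation.
#' @param n_per_group subjects per group; group 1 ages 19-37 years, group 2
#'   42-73.
#' @param T_bold BOLD samples per subject.
#' @param coupling lag-1 VAR coupling for the BOLD fixture (default: one
#'   planted directed edge from the first ROI to the second, weight 0.5).
#' @param edge_prob probability that a subject expresses a structural edge.
#' @param mean_fibers mean planted fiber count per expressed edge.
#' @param group_effects morphometry shifts for group 2
#'   (see [make_group_morphometry()]).
#' @param seed master RNG seed.
#' @return the study root path, invisibly.
#' @export
write_synthetic_study <- function(root, n_rois = 8, n_per_group = c(15, 20),
                                  T_bold = 120, coupling = NULL,
                                  edge_prob = 0.9, mean_fibers = 10,
                                  group_effects = list(CT = -0.5), seed = 1) {
  local_seed(seed)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  parc <- make_toy_parcellation(n_rois)
  write_label_volume(parc, file.path(root, "parcellation.nii.gz"))
  ids <- roi_ids_of(parc)
  n_sub <- sum(n_per_group)
  sids <- sprintf("S%02d", seq_len(n_sub))
  group <- rep(1:2, n_per_group)
  ages <- ifelse(group == 1, sample(19:37, n_sub, replace = TRUE),
                 sample(42:73, n_sub, replace = TRUE))
  sex <- sample(c("M", "F"), n_sub, replace = TRUE)
  utils::write.table(
    data.frame(subject_id = sids, age = ages, sex = sex, group = group),
    file.path(root, "participants.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  if (is.null(coupling)) {
    coupling <- matrix(0, n_rois, n_rois)
    coupling[2, 1] <- 0.5
  }
  # candidate structural edges: a fixed random half of all pairs
  pairs <- t(utils::combn(ids, 2))
  on_edge <- sample(c(TRUE, FALSE), nrow(pairs), replace = TRUE)
  morph <- make_group_morphometry(parc, n_per_group,
                                  group_effects = group_effects,
                                  seed = sample.int(2^30, 1))
  truth <- list(seed = seed, coupling = coupling, group = group,
                group_effects = group_effects,
                fiber_counts = list())
  for (s in seq_len(n_sub)) {
    sdir <- file.path(root, sids[s])
    for (acq in c("aMRI", "dMRI", "fMRI", "PET"))
      dir.create(file.path(sdir, acq, "run1"), recursive = TRUE,
                 showWarnings = FALSE)
    write_morphometry(morph$tables[[s]],
                      file.path(sdir, "aMRI", "run1", "morphometry.tsv"))
    present <- on_edge & stats::runif(nrow(pairs)) < edge_prob
    counts <- data.frame(roi_a = pairs[present, 1], roi_b = pairs[present, 2],
                         count = 1 + stats::rpois(sum(present), mean_fibers - 1))
    tract <- make_streamlines(parc, counts, n_orphans = 2,
                              seed = sample.int(2^30, 1))
    write_tractogram(tract, file.path(sdir, "dMRI", "run1", "tracts.trk"))
    truth$fiber_counts[[sids[s]]] <- counts
    bold <- make_var_timeseries(n_rois, T_bold, coupling,
                                seed = sample.int(2^30, 1))
    bold$roi_ids <- ids
    bold$roi_names <- roi_names_of(parc)
    write_signals(roi_signals(bold$values, ids, sampling = 2,
                              modality = "bold",
                              roi_names = roi_names_of(parc)),
                  file.path(sdir, "fMRI", "run1", "bold.tsv"))
    tacs <- make_pet_tacs(parc, seed = sample.int(2^30, 1))
    write_signals(tacs, file.path(sdir, "PET", "run1", "tacs.tsv"))
  }
  jsonlite::write_json(
    list(seed = seed, n_rois = n_rois, group = group,
         group_effects = group_effects, coupling = coupling,
         fiber_counts = truth$fiber_counts),
    file.path(root, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(root)
}
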