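# Batch orchestration: per-subject connectivity, group assembly, statistics
# and figures, driven by a single config whose defaults are the analysis
# constants used throughout (alpha 0.05, robustness threshold 0.8, Granger
# order 1, 10 null graphs).

#' Pipeline configuration
#'
#' @param ... overrides of the defaults: `alpha` (0.05), `robustness_tau`
#'   (0.8), `granger_order` (1), `n_null_graphs` (10), `seed` (1),
#'   `pet_reference_roi` (NULL = first subcortical ROI), `group_variable`
#'   ("age"), `group_threshold` (40), `regress` (character of covariates to
#'   residualize, default none), `correction` ("none"), `stages`
#'   (c("amri","dmri","fmri","pet")), `figures` (TRUE).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(list(
    alpha = 0.05, robustness_tau = 0.8, granger_order = 1,
    n_null_graphs = 10, seed = 1, pet_reference_roi = NULL,
    group_variable = "age", group_threshold = 40, regress = character(0),
    correction = "none", stages = c("amri", "dmri", "fmri", "pet"),
    figures = TRUE), list(...))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `path` / a [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

find_input <- function(run_paths, pattern) {
  for (rp in run_paths) {
    hits <- list.files(rp, pattern = pattern, full.names = TRUE)
    if (length(hits)) return(hits[1])
  }
  NULL
}

#' Run the connectivity stages for one subject
#'
#' Every stage whose inputs exist runs; missing modalities are skipped with
#' a logged notice. Outputs land in per-modality folders under
#' `out_dir/<subject>/`.
#'
#' @param subject_id subject identifier.
#' @param acquisitions named list acquisition kind -> run paths (one entry
#'   of a [discover_study_tree()] index).
#' @param parc the shared [parcellation()].
#' @param out_dir output root.
#' @param config a [pipeline_config()].
#' @return list of per-stage status (`"ok"`, `"skipped"` or the error
#'   message), invisibly.
#' @export
run_subject <- function(subject_id, acquisitions, parc, out_dir,
                        config = pipeline_config()) {
  sdir <- file.path(out_dir, subject_id)
  status <- list()
  log <- function(stage, st)
    message(sprintf("[%s] %s: %s", subject_id, stage, st))
  stage <- function(name, enabled, fn) {
    if (!enabled) { status[[name]] <<- "skipped"; log(name, "skipped"); return() }
    status[[name]] <<- tryCatch({ fn(); "ok" },
                                error = function(e) conditionMessage(e))
    log(name, status[[name]])
  }
  morph_path <- find_input(acquisitions$amri, "morphometry\\.tsv$")
  morph <- if (!is.null(morph_path)) read_morphometry(morph_path) else NULL

  stage("amri", "amri" %in% config$stages && !is.null(morph), function() {
    dir.create(file.path(sdir, "aMRI"), recursive = TRUE, showWarnings = FALSE)
    for (ms in c("CT", "SA", "GMV"))
      write_matrix(anatomical_cm(morph, ms),
                   file.path(sdir, "aMRI", paste0("a_cm_", ms, ".tsv")))
    if (sum(morph$tissue_class == "subcortical") >= 2)
      write_matrix(anatomical_cm(morph, "volume"),
                   file.path(sdir, "aMRI", "a_cm_volume.tsv"))
  })

  trk_path <- find_input(acquisitions$dmri, "\\.(trk|txt)$")
  stage("dmri", "dmri" %in% config$stages && !is.null(trk_path), function() {
    dir.create(file.path(sdir, "dMRI"), recursive = TRUE, showWarnings = FALSE)
    tract <- read_tractogram(trk_path)
    sres <- structural_cm(assign_streamlines(tract, parc), parc)
    write_matrix(sres$count, file.path(sdir, "dMRI", "s_cm.tsv"))
    write_matrix(sres$length, file.path(sdir, "dMRI", "length_cm.tsv"))
    if (!is.null(morph) && all(c("FA", "MD") %in% names(morph))) {
      dm <- data.frame(label_id = roi_ids_of(parc),
                       name = roi_names_of(parc),
                       FA = roi_scalar_means(morph, parc, "FA"),
                       MD = roi_scalar_means(morph, parc, "MD"))
      utils::write.table(dm, file.path(sdir, "dMRI", "diffusion_means.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  })

  bold_path <- find_input(acquisitions$fmri, "bold\\.tsv$")
  stage("fmri", "fmri" %in% config$stages && !is.null(bold_path), function() {
    dir.create(file.path(sdir, "fMRI"), recursive = TRUE, showWarnings = FALSE)
    sig <- read_signals(bold_path)
    fc <- pearson_fc(sig)
    thr <- threshold_bonferroni(fc, alpha = config$alpha)
    write_matrix(fc$r, file.path(sdir, "fMRI", "f_r.tsv"))
    utils::write.table(fc$p, file.path(sdir, "fMRI", "f_p.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    write_matrix(thr$binary, file.path(sdir, "fMRI", "f_binary.tsv"))
    write_matrix(thr$weighted, file.path(sdir, "fMRI", "f_weighted.tsv"))
    ec <- effective_cm(sig, order = config$granger_order, alpha = config$alpha)
    write_matrix(ec$gc, file.path(sdir, "fMRI", "e_gc.tsv"))
    write_matrix(ec$binary, file.path(sdir, "fMRI", "e_binary.tsv"))
  })

  tac_path <- find_input(acquisitions$pet, "tacs\\.tsv$")
  stage("pet", "pet" %in% config$stages && !is.null(tac_path), function() {
    dir.create(file.path(sdir, "PET"), recursive = TRUE, showWarnings = FALSE)
    tacs <- read_signals(tac_path)
    pc <- suppressWarnings(pet_cm(tacs))
    write_matrix(pc$r, file.path(sdir, "PET", "pet_cm.tsv"))
    ref <- config$pet_reference_roi
    if (is.null(ref)) ref <- roi_ids_of(parc)[1]
    utils::write.table(roi_suv_from_tacs(tacs, ref),
                       file.path(sdir, "PET", "suv.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  })
  invisible(status)
}

read_subject_matrix <- function(out_dir, sid, rel) {
  p <- file.path(out_dir, sid, rel)
  if (!file.exists(p)) return(NULL)
  read_matrix(p)
}

#' Run the full group analysis over a study
#'
#' Discovers the study tree, processes every subject, assembles per-modality
#' subject stacks, and writes the group artifact set: mean / robustness /
#' combined matrices for structural and functional connectivity, the hybrid
#' sf matrices, the direct/mediated decomposition of the group binaries,
#' graph-metric reports with null-model normalization, between-group tests
#' on morphometry, figures, and a run manifest.
#'
#' @param study_root study directory (Study-Subject-Acquisition layout, with
#'   `parcellation.nii.gz` and `participants.tsv` at the root).
#' @param out_dir output root.
#' @param config a [pipeline_config()].
#' @return list with the group objects (stacks, group matrices, graph
#'   reports, test table, per-subject status), invisibly.
#' @export
run_group <- function(study_root, out_dir, config = pipeline_config()) {
  index <- discover_study_tree(study_root)
  # subject folders only: ignore non-subject entries at the root
  parc <- read_label_volume(file.path(study_root, "parcellation.nii.gz"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  for (sid in names(index$subjects)) {
    if (!length(index$subjects[[sid]])) next
    status[[sid]] <- run_subject(sid, index$subjects[[sid]], parc, out_dir,
                                 config)
  }
  ok <- names(status)[vapply(status, function(s)
    any(unlist(s) == "ok"), FALSE)]
  if (!length(ok)) stop("no subjects processed successfully")
  gdir <- file.path(out_dir, "group")
  dir.create(gdir, showWarnings = FALSE)
  out <- list(status = status)

  collect <- function(rel) {
    mats <- lapply(ok, function(sid) read_subject_matrix(out_dir, sid, rel))
    names(mats) <- ok
    mats[!vapply(mats, is.null, TRUE)]
  }
  group_set <- function(weighted, binary, tag) {
    st_w <- subject_stack(weighted)
    st_b <- subject_stack(binary)
    mean_m <- mean_cm(st_w)
    rob <- robustness_cm(st_b)
    comb <- combined_cm(mean_m, rob, tau = config$robustness_tau)
    write_matrix(mean_m, file.path(gdir, paste0(tag, "_mean.tsv")))
    write_matrix(rob, file.path(gdir, paste0(tag, "_robustness.tsv")))
    write_matrix(comb, file.path(gdir, paste0(tag, "_combined.tsv")))
    list(mean = mean_m, robustness = rob, combined = comb)
  }

  s_mats <- collect(file.path("dMRI", "s_cm.tsv"))
  f_w <- collect(file.path("fMRI", "f_weighted.tsv"))
  f_b <- collect(file.path("fMRI", "f_binary.tsv"))
  if (length(s_mats))
    out$s <- group_set(s_mats, lapply(s_mats, binarize, rule = "positive_count"), "s")
  if (length(f_w) && length(f_b)) out$f <- group_set(f_w, f_b, "f")

  if (length(s_mats) && length(f_w)) {
    common <- intersect(names(s_mats), names(f_w))
    sf <- lapply(common, function(sid) hybrid_sf(s_mats[[sid]], f_w[[sid]]))
    names(sf) <- common
    out$sf_mean <- mean_cm(subject_stack(sf))
    write_matrix(out$sf_mean, file.path(gdir, "sf_mean.tsv"))
  }

  graph_report <- function(bin, tag, seed_off) {
    if (sum(bin$values) == 0) {
      message("group ", tag, " graph is empty; metrics skipped")
      return(NULL)
    }
    sw <- small_worldness(bin, n_null = config$n_null_graphs,
                          seed = config$seed + seed_off)
    mod <- graph_modularity(bin, seed = config$seed + seed_off)
    deg <- graph_degree(bin); cc <- clustering_coefficient(bin)
    cpl <- characteristic_path_length(bin)
    utils::write.table(
      data.frame(name = bin$roi_names, degree = deg$per_node,
                 clustering = cc$per_node, community = mod$partition),
      file.path(gdir, paste0(tag, "_nodes.tsv")), sep = "\t",
      row.names = FALSE, quote = FALSE)
    rep <- list(mean_degree = deg$mean, mean_clustering = cc$mean,
                char_path_length = cpl$L,
                unreachable_frac = cpl$unreachable_frac,
                small_worldness = sw$sigma, normalized = as.list(sw$normalized),
                modularity_Q = mod$Q, n_null = config$n_null_graphs,
                seed = config$seed + seed_off)
    jsonlite::write_json(rep, file.path(gdir, paste0(tag, "_graph.json")),
                         auto_unbox = TRUE, digits = NA)
    rep
  }
  binaries <- list()
  if (!is.null(out$s)) {
    binaries$s <- binarize(conn_matrix(
      (out$s$robustness$values > config$robustness_tau) * 1,
      out$s$robustness$roi_ids, modality = "s", weight_kind = "binary",
      roi_names = out$s$robustness$roi_names), "positive_count")
    out$graph_s <- tryCatch(graph_report(binaries$s, "s", 11),
                            error = function(e) { message(conditionMessage(e)); NULL })
  }
  if (!is.null(out$f)) {
    binaries$f <- binarize(conn_matrix(
      (out$f$robustness$values > config$robustness_tau) * 1,
      out$f$robustness$roi_ids, modality = "f", weight_kind = "binary",
      roi_names = out$f$robustness$roi_names), "positive_count")
    out$graph_f <- tryCatch(graph_report(binaries$f, "f", 13),
                            error = function(e) { message(conditionMessage(e)); NULL })
  }
  if (length(binaries) == 2) {
    out$decomposition <- decompose_direct_mediated(binaries$s, binaries$f)
    write_matrix(out$decomposition$direct, file.path(gdir, "sf_direct.tsv"))
    write_matrix(out$decomposition$mediated, file.path(gdir, "sf_mediated.tsv"))
  }

  pt_path <- file.path(study_root, "participants.tsv")
  if (file.exists(pt_path)) {
    participants <- utils::read.delim(pt_path, stringsAsFactors = FALSE)
    participants <- participants[participants$subject_id %in% ok, , drop = FALSE]
    morphs <- lapply(participants$subject_id, function(sid) {
      p <- find_input(index$subjects[[sid]]$amri, "morphometry\\.tsv$")
      if (!is.null(p)) read_morphometry(p) else NULL
    })
    keep <- !vapply(morphs, is.null, TRUE)
    if (sum(keep) >= 4) {
      participants <- participants[keep, , drop = FALSE]
      morphs <- morphs[keep]
      sp <- split_groups(participants, config$group_variable,
                         config$group_threshold)
      tests <- list()
      for (ms in c("CT", "GMV", "volume", "FA", "MD")) {
        vals <- t(vapply(morphs, function(m) m[[ms]], numeric(nrow(morphs[[1]]))))
        colnames(vals) <- paste0(ms, ":", morphs[[1]]$name)
        okcol <- colSums(is.na(vals)) == 0
        if (!any(okcol)) next
        cov_a <- cov_b <- NULL
        if (length(config$regress)) {
          cov_a <- participants[sp$group1, config$regress, drop = FALSE]
          cov_b <- participants[sp$group2, config$regress, drop = FALSE]
        }
        tests[[ms]] <- groupwise_test(vals[sp$group1, okcol, drop = FALSE],
                                      vals[sp$group2, okcol, drop = FALSE],
                                      covariates_a = cov_a, covariates_b = cov_b,
                                      correction = config$correction,
                                      alpha = config$alpha)
      }
      out$group_tests <- do.call(rbind, tests)
      utils::write.table(out$group_tests, file.path(gdir, "group_tests.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  if (isTRUE(config$figures)) {
    fdir <- file.path(out_dir, "figures")
    if (!is.null(out$s)) {
      matrix_plot(out$s$mean, parc, file.path(fdir, "s_mean.pdf"))
      matrix_plot(out$s$robustness, parc, file.path(fdir, "s_robustness.pdf"))
    }
    if (!is.null(out$decomposition)) {
      deg <- graph_degree(binaries$s)$per_node
      connectogram(out$decomposition, parc,
                   rings = list(degree = as.numeric(deg)),
                   edge_color_mode = "by_class",
                   out_path = file.path(fdir, "sf_connectogram.pdf"))
      graph3d(binaries$s, parc = parc, out_path = file.path(fdir, "s_graph3d.pdf"))
    }
  }

  jsonlite::write_json(
    list(package = "neuroconn",
         version = as.character(utils::packageVersion("neuroconn")),
         seed = config$seed,
         config = unclass(config)[setdiff(names(config), "stages")],
         subjects = names(status),
         processed = ok, timepoint = "run manifest"),
    file.path(gdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
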