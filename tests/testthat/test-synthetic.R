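test_that("toy parcellation plants mirrored boxes with valid table", {
  parc <- make_toy_parcellation(8, shape = c(20, 20, 20))
  expect_equal(nrow(parc$roi_table), 8)
  expect_equal(sum(parc$roi_table$hemisphere == "left"), 4)
  labs <- setdiff(unique(as.vector(parc$labels)), 0L)
  expect_setequal(labs, 1:8)
  # boxes are disjoint: each label occupies exactly 8 voxels
  expect_true(all(table(parc$labels[parc$labels > 0]) == 8))
  # mirror symmetry of the label support across the mid-sagittal plane
  d <- dim(parc$labels)
  flipped <- parc$labels[d[1]:1, , ]
  expect_equal(flipped > 0, parc$labels > 0)
  expect_error(make_toy_parcellation(3), "even")
  expect_error(make_toy_parcellation(200, shape = c(10, 10, 10)), "fit")
  expect_identical(make_toy_parcellation(8, seed = 9)$labels,
                   make_toy_parcellation(8, seed = 9)$labels)
})

test_that("planted streamline endpoints agree with their pair counts", {
  parc <- toy_parc8()
  counts <- data.frame(roi_a = c(1, 1, 3), roi_b = c(2, 4, 5),
                       count = c(3, 1, 2))
  tr <- make_streamlines(parc, counts, n_orphans = 5, seed = 2)
  expect_length(tr$streamlines, sum(counts$count) + 5)
  # endpoint membership re-derived by voxel lookup matches the plan exactly
  a <- assign_streamlines(tr, parc)
  got <- table(paste(pmin(a$roi_start, a$roi_end),
                     pmax(a$roi_start, a$roi_end))[a$assigned])
  want <- stats::setNames(counts$count, paste(counts$roi_a, counts$roi_b))
  expect_mapequal(as.list(got), as.list(want))
  expect_equal(sum(!a$assigned), 5)
  expect_error(make_streamlines(parc, data.frame(roi_a = 99, roi_b = 1,
                                                 count = 1)), "absent")
})

test_that("VAR generator is stationary, seeded and has the planted moments", {
  # no coupling: pairwise correlations vanish at large T
  sig0 <- make_var_timeseries(4, 2000, seed = 21)
  r <- stats::cor(t(sig0$values))
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)
  # planted lag-1 coupling y <- 0.9 x: corr(x_{t-1}, y_t) = 0.9/sqrt(1.81)
  A <- matrix(0, 2, 2); A[2, 1] <- 0.9
  sig <- make_var_timeseries(2, 5000, A, seed = 22)
  x <- sig$values[1, ]; y <- sig$values[2, ]
  lag_r <- stats::cor(x[-length(x)], y[-1])
  expect_equal(lag_r, 0.9 / sqrt(1 + 0.81), tolerance = 0.05)
  # determinism and stationarity guard
  expect_identical(make_var_timeseries(3, 50, seed = 5)$values,
                   make_var_timeseries(3, 50, seed = 5)$values)
  expect_error(make_var_timeseries(2, 50, diag(2) * 1.1), "non-stationary")
})

test_that("group morphometry plants recoverable effects", {
  parc <- toy_parc8()
  # null effects: both groups share the distribution
  g0 <- make_group_morphometry(parc, c(5, 5), seed = 3)
  expect_length(g0$tables, 10)
  expect_equal(g0$group, rep(1:2, each = 5))
  # planted CT decrease of 0.5 mm recovered within 3 standard errors
  eff <- list(CT = -0.5)
  g1 <- make_group_morphometry(parc, c(15, 20), group_effects = eff,
                               noise_sd = list(CT = 0.2), seed = 4)
  ct <- vapply(g1$tables, function(t) mean(t$CT, na.rm = TRUE), 0)
  diffm <- mean(ct[g1$group == 2]) - mean(ct[g1$group == 1])
  n_cort <- sum(parc$roi_table$tissue_class == "cortical")
  se <- 0.2 / sqrt(n_cort) * sqrt(1 / 15 + 1 / 20)
  expect_lt(abs(diffm - (-0.5)), 3 * se)
  # physical ranges hold
  for (tb in g1$tables) {
    expect_true(all(tb$FA <= 1 & tb$FA >= 0))
    expect_true(all(tb$CT[!is.na(tb$CT)] > 0))
  }
  expect_error(make_group_morphometry(parc, c(1, 5)), "at least 2")
  expect_error(make_group_morphometry(parc, c(5, 5),
                                      baseline = list(CT = -1)), "positive")
})

test_that("PET TAC generator hits its correlation limits", {
  parc <- toy_parc8()
  prof <- matrix(c(1, 3, 7, 6, 4, 2, 1, 0.5), 1)
  shared <- make_pet_tacs(parc, kinetic_profiles = prof, noise_sd = 1e-6,
                          seed = 6)
  r <- stats::cor(t(shared$values))
  expect_gt(min(r), 0.999)
  # orthogonalized profiles decorrelate as noise vanishes
  p1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  p2 <- c(1, 1, -1, -1, 1, 1, -1, -1)  # zero-mean, orthogonal to p1
  orth <- make_pet_tacs(parc, kinetic_profiles = rbind(p1, p2),
                        noise_sd = 1e-6, seed = 7)
  expect_lt(abs(stats::cor(orth$values[1, ], orth$values[2, ])), 0.01)
  expect_identical(make_pet_tacs(parc, seed = 8)$values,
                   make_pet_tacs(parc, seed = 8)$values)
  expect_equal(ncol(make_pet_tacs(parc, seed = 1)$values), 8)
})

test_that("synthetic study tree conforms to the layout and its manifest", {
  root <- file.path(withr::local_tempdir(), "study")
  write_synthetic_study(root, n_rois = 6, n_per_group = c(2, 3), T_bold = 40,
                        seed = 12)
  idx <- discover_study_tree(root)
  expect_length(idx$subjects, 5)
  expect_setequal(names(idx$subjects$S01), c("amri", "dmri", "fmri", "pet"))
  truth <- jsonlite::read_json(file.path(root, "truth.json"))
  expect_equal(truth$n_rois, 6)
  expect_length(truth$fiber_counts, 5)
  pt <- utils::read.delim(file.path(root, "participants.tsv"))
  expect_equal(nrow(pt), 5)
  expect_true(all(pt$age[pt$group == 1] < 40) && all(pt$age[pt$group == 2] > 40))
})
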