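test_that("endpoint assignment does plain voxel geometry", {
  parc <- toy_parc8()
  # voxel centers of two labelled voxels 10 mm apart along y? use actual boxes:
  # label 1 occupies x 1..2 (0-based), label 3 occupies a disjoint box.
  v1 <- which(parc$labels == 1L, arr.ind = TRUE)[1, ] - 1
  v2 <- which(parc$labels == 3L, arr.ind = TRUE)[1, ] - 1
  tr <- tractogram(list(rbind(v1 + 0.5, v2 + 0.5)))
  a <- assign_streamlines(tr, parc)
  expect_equal(a$roi_start, 1L)
  expect_equal(a$roi_end, 3L)
  expect_equal(a$length_mm, sqrt(sum((v1 - v2)^2)))
  expect_true(a$assigned)
  # straight 2-point line of known length
  tr10 <- tractogram(list(rbind(v1 + 0.5, v1 + 0.5 + c(0, 10, 0))))
  expect_equal(assign_streamlines(tr10, parc)$length_mm, 10)
  # background endpoint is unassigned
  bg <- which(parc$labels == 0L, arr.ind = TRUE)[1, ] - 1
  tro <- tractogram(list(rbind(v1 + 0.5, bg + 0.5)))
  expect_false(assign_streamlines(tro, parc)$assigned)
})

test_that("assignments equal brute-force per-point voxel lookup", {
  parc <- toy_parc8()
  set.seed(41)
  sl <- lapply(1:40, function(i)
    matrix(stats::runif(3 * sample(2:6, 1), -2, 26), ncol = 3))
  a <- assign_streamlines(tractogram(sl), parc)
  d <- dim(parc$labels)
  look <- function(p) {
    v <- floor(p)
    if (any(v < 0) || any(v >= d)) return(NA_integer_)
    l <- parc$labels[v[1] + 1, v[2] + 1, v[3] + 1]
    if (l == 0) NA_integer_ else l
  }
  for (i in seq_along(sl)) {
    expect_identical(a$roi_start[i], look(sl[[i]][1, ]))
    expect_identical(a$roi_end[i], look(sl[[i]][nrow(sl[[i]]), ]))
    expect_equal(a$length_mm[i], sum(sqrt(rowSums(diff(sl[[i]])^2))))
  }
})

test_that("structural matrices recover planted counts and means", {
  parc <- toy_parc8()
  counts <- data.frame(roi_a = c(1, 1), roi_b = c(2, 4), count = c(3, 1))
  tr <- make_streamlines(parc, counts, seed = 5)
  s <- structural_cm(assign_streamlines(tr, parc), parc)
  ids <- parc$roi_table$label_id
  expect_equal(s$count$values[match(1, ids), match(2, ids)], 3)
  expect_equal(s$count$values[match(1, ids), match(4, ids)], 1)
  expect_equal(sum(s$count$values), 2 * 4)  # symmetric tally
  # mean length: two fibers of 8 and 12 mm between one pair average to 10
  a2 <- data.frame(roi_start = c(1L, 1L), roi_end = c(2L, 2L),
                   length_mm = c(8, 12), dx = 1, dy = 0, dz = 0,
                   assigned = TRUE)
  s2 <- structural_cm(a2, parc)
  expect_equal(s2$length$values[match(1, ids), match(2, ids)], 10)
  expect_equal(s2$count$values[match(1, ids), match(2, ids)], 2)
})

test_that("structural tally matches brute force and its invariants", {
  parc <- toy_parc8()
  set.seed(43)
  for (draw in 1:5) {
    pairs <- t(utils::combn(1:8, 2))
    sel <- sample(nrow(pairs), 5)
    counts <- data.frame(roi_a = pairs[sel, 1], roi_b = pairs[sel, 2],
                         count = sample(1:4, 5, replace = TRUE))
    tr <- make_streamlines(parc, counts, n_orphans = 3, seed = 100 + draw)
    a <- assign_streamlines(tr, parc)
    s <- structural_cm(a, parc)
    ids <- parc$roi_table$label_id
    # brute-force tally over the assignment table
    want <- matrix(0, 8, 8)
    for (r in which(a$assigned)) {
      i <- match(a$roi_start[r], ids); j <- match(a$roi_end[r], ids)
      if (i != j) { want[i, j] <- want[i, j] + 1; want[j, i] <- want[j, i] + 1 }
    }
    expect_equal(unname(s$count$values), want)
    # conservation: upper-triangle sum = assigned non-loop streamlines
    expect_equal(sum(s$count$values[upper.tri(want)]), s$qc$n_assigned)
    # reversal invariance
    trR <- tractogram(lapply(tr$streamlines, function(m) m[nrow(m):1, ]))
    sR <- structural_cm(assign_streamlines(trR, parc), parc)
    expect_equal(sR$count$values, s$count$values)
    # length-count support agreement
    expect_equal(s$length$values > 0, s$count$values > 0)
  }
})

test_that("ROI scalar means equal the brute-force masked average", {
  parc <- toy_parc8()
  const <- array(0.4, dim(parc$labels))
  m <- roi_scalar_means(const, parc)
  expect_equal(unname(m), rep(0.4, 8))
  set.seed(44)
  vol <- array(stats::runif(prod(dim(parc$labels))), dim(parc$labels))
  m2 <- roi_scalar_means(vol, parc)
  for (r in seq_len(8)) {
    id <- parc$roi_table$label_id[r]
    expect_equal(unname(m2[r]), mean(vol[parc$labels == id]))
  }
  expect_error(roi_scalar_means(array(1, c(2, 2, 2)), parc), "grid")
  # table path validates completeness
  tab <- data.frame(label_id = parc$roi_table$label_id, FA = stats::runif(8))
  expect_equal(unname(roi_scalar_means(tab, parc, "FA")),
               tab$FA[match(parc$roi_table$label_id, tab$label_id)])
  expect_error(roi_scalar_means(tab[-1, ], parc, "FA"), "missing")
})
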