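# Static renderers for the three standard views: block-ordered matrix
# heatmap, multi-ring connectogram, and a projected 3D brain graph.
# Each renderer writes a file (device chosen by extension: .pdf vector,
# .png raster) and invisibly returns the structural metadata the tests
# check (orderings, chord/edge counts).

#' Jet-style colormap
#'
#' Cold colors for low values, warm for high.
#'
#' @param n number of colors.
#' @return character vector of colors.
#' @export
jet_colors <- function(n = 64) {
  grDevices::colorRampPalette(c("#00007F", "blue", "#007FFF", "cyan",
                                "#7FFF7F", "yellow", "#FF7F00", "red",
                                "#7F0000"))(n)
}

open_device <- function(path, width = 7, height = 7) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (grepl("\\.png$", path)) grDevices::png(path, width * 100, height * 100)
  else grDevices::pdf(path, width = width, height = height)
}

#' Block-ordered connectivity matrix heatmap
#'
#' Renders the matrix with rows/columns in the canonical block order
#' (I subcortical left/right, II left cortical, III right cortical), jet
#' colormap, and lines at the block boundaries.
#'
#' @param cm a [conn_matrix()].
#' @param parc the [parcellation()] defining blocks and order.
#' @param out_path output image (.pdf or .png).
#' @return invisibly, list with `order` (ROI names as drawn) and `blocks`
#'   (block sizes).
#' @export
matrix_plot <- function(cm, parc, out_path) {
  stopifnot_conn(cm)
  ids <- roi_ids_of(parc)
  idx <- match(ids, cm$roi_ids)
  if (any(is.na(idx))) stop("matrix does not cover the parcellation ROIs")
  v <- cm$values[idx, idx]
  rt <- parc$roi_table
  blocks <- c(I = sum(rt$tissue_class == "subcortical"),
              II = sum(rt$tissue_class == "cortical" & rt$hemisphere == "left"),
              III = sum(rt$tissue_class == "cortical" & rt$hemisphere == "right"))
  R <- nrow(v)
  open_device(out_path)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 6, 2, 1))
  # image() draws x right, y up; flip rows so row 1 appears on top
  graphics::image(seq_len(R), seq_len(R), t(v[R:1, ]), col = jet_colors(),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste0(cm$modality, "-CM"))
  graphics::axis(1, at = seq_len(R), labels = rt$name, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(R), labels = rev(rt$name), las = 2, cex.axis = 0.6)
  for (b in cumsum(blocks)[1:2]) {
    graphics::abline(v = b + 0.5, lwd = 2)
    graphics::abline(h = R - b + 0.5, lwd = 2)
  }
  graphics::box()
  invisible(list(order = rt$name, blocks = blocks))
}

chord_color <- function(mode, weight, class) {
  # Methods-text convention: red = increase/positive, blue = decrease/negative;
  # class colors: direct red, mediated blue (configurable upstream).
  switch(mode,
         by_sign = if (weight >= 0) "red" else "blue",
         by_class = if (class == "direct") "red" else "blue",
         by_weight = grDevices::adjustcolor("grey30", alpha.f = 0.8))
}

#' Multi-ring connectogram
#'
#' Circular layout with one sector per ROI in canonical order, hemisphere
#' sectors shaded in two grays on the outer ring, optional concentric
#' metric rings (values mapped to the jet colormap), and chords for every
#' nonzero edge. Edge colors follow `edge_color_mode`: `"by_sign"` paints
#' positive/increase red and negative/decrease blue; `"by_class"` paints
#' direct connections with `class_colors[1]` and mediated with
#' `class_colors[2]`; `"by_weight"` uses a neutral ramp.
#'
#' @param edges a [conn_matrix()], or for `by_class` a list with binary
#'   elements `direct` and `mediated`.
#' @param parc the [parcellation()].
#' @param rings named list of per-ROI numeric vectors (canonical order),
#'   outermost first.
#' @param edge_color_mode `"by_sign"`, `"by_class"` or `"by_weight"`.
#' @param class_colors colors for direct/mediated chords.
#' @param out_path output image (.pdf or .png).
#' @return invisibly, list with `n_chords` (per class when `by_class`) and
#'   `sector_order`.
#' @export
connectogram <- function(edges, parc, rings = list(),
                         edge_color_mode = c("by_sign", "by_class", "by_weight"),
                         class_colors = c(direct = "red", mediated = "blue"),
                         out_path) {
  edge_color_mode <- match.arg(edge_color_mode)
  rt <- parc$roi_table
  R <- nrow(rt)
  for (nm in names(rings))
    if (length(rings[[nm]]) != R)
      stop("ring metric '", nm, "' not defined for every ROI")
  if (edge_color_mode == "by_class") {
    if (!is.list(edges) || !all(c("direct", "mediated") %in% names(edges)))
      stop("by_class mode needs list(direct=, mediated=)")
    mats <- list(direct = edges$direct$values, mediated = edges$mediated$values)
  } else {
    stopifnot_conn(edges)
    mats <- list(all = edges$values)
  }
  theta <- pi - 2 * pi * (seq_len(R) - 0.5) / R  # clockwise from the left
  px <- cos(theta); py <- sin(theta)
  open_device(out_path)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.7, 1.7), ylim = c(-1.7, 1.7), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = "connectogram")
  shade <- ifelse(rt$hemisphere == "right", "grey40", "grey75")
  arc <- function(r0, r1, i, col) {
    a <- -2 * pi * (i - 1) / R + pi; b <- -2 * pi * i / R + pi
    tt <- seq(a, b, length.out = 12)
    graphics::polygon(c(r0 * cos(tt), r1 * cos(rev(tt))),
                      c(r0 * sin(tt), r1 * sin(rev(tt))),
                      col = col, border = NA)
  }
  for (i in seq_len(R)) arc(1.05, 1.15, i, shade[i])
  jc <- jet_colors(32)
  rr <- 1.03
  for (nm in names(rings)) {
    v <- rings[[nm]]
    rng <- range(v)
    sc <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, R)
    for (i in seq_len(R)) arc(rr - 0.06, rr, i, jc[1 + floor(sc[i] * 31)])
    rr <- rr - 0.08
  }
  graphics::text(1.25 * px, 1.25 * py, rt$name, cex = 0.5,
                 srt = 0, xpd = NA)
  n_chords <- integer(0)
  for (cls in names(mats)) {
    m <- mats[[cls]]
    cnt <- 0L
    for (i in seq_len(R - 1)) for (j in (i + 1):R) {
      w <- if (m[i, j] != 0) m[i, j] else m[j, i]
      if (w == 0) next
      cnt <- cnt + 1L
      col <- if (edge_color_mode == "by_class") class_colors[[cls]]
             else chord_color(edge_color_mode, w, cls)
      r_in <- rr
      graphics::xspline(c(px[i] * r_in, 0, px[j] * r_in),
                        c(py[i] * r_in, 0, py[j] * r_in),
                        shape = 1, border = col, lwd = 1)
    }
    n_chords[cls] <- cnt
  }
  invisible(list(n_chords = n_chords, sector_order = rt$name))
}

#' Projected 3D brain graph
#'
#' Draws ROIs at their mm coordinates (axial projection: x versus y,
#' depth coded by marker shading), node markers scaled monotonically with a
#' per-node metric, and edges for every nonzero entry. For directed
#' matrices, one-way connections render as red-to-blue gradient lines (red
#' at the source) and bidirectional connections as solid black lines.
#'
#' @param cm a [conn_matrix()].
#' @param node_coords ROI x 3 matrix of mm coordinates (defaults to the
#'   parcellation centroids when `parc` is given).
#' @param metrics per-node scalar controlling marker size (default degree).
#' @param parc optional [parcellation()] supplying coordinates.
#' @param out_path output image (.pdf or .png).
#' @return invisibly, list with `n_edges`, `n_bidirectional`, `sizes`.
#' @export
graph3d <- function(cm, node_coords = NULL, metrics = NULL, parc = NULL,
                    out_path) {
  stopifnot_conn(cm)
  if (is.null(node_coords)) {
    if (is.null(parc)) stop("missing coordinates: supply node_coords or parc")
    cen <- roi_centroids(parc)
    node_coords <- cen[match(cm$roi_ids, roi_ids_of(parc)), , drop = FALSE]
  }
  node_coords <- as.matrix(node_coords)
  if (nrow(node_coords) != n_rois(cm)) stop("one coordinate row per ROI required")
  R <- n_rois(cm)
  if (is.null(metrics)) {
    a <- (cm$values != 0) * 1
    metrics <- rowSums(a | t(a))
  }
  rngm <- range(metrics)
  sizes <- 1 + 3 * if (diff(rngm) > 0) (metrics - rngm[1]) / diff(rngm) else rep(0.5, R)
  open_device(out_path)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 2, 1))
  graphics::plot(node_coords[, 1], node_coords[, 2], cex = sizes, pch = 19,
                 col = grDevices::grey(0.2 + 0.6 *
                   (rank(node_coords[, 3]) - 1) / max(1, R - 1)),
                 xlab = "x (mm)", ylab = "y (mm)", main = "3D graph (axial)")
  n_edges <- 0L; n_bi <- 0L
  grad <- grDevices::colorRampPalette(c("red", "blue"))(10)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    fij <- cm$values[i, j] != 0; fji <- cm$values[j, i] != 0
    if (!fij && !fji) next
    n_edges <- n_edges + 1L
    if (cm$directed && fij && fji) {
      n_bi <- n_bi + 1L
      graphics::segments(node_coords[i, 1], node_coords[i, 2],
                         node_coords[j, 1], node_coords[j, 2],
                         col = "black", lwd = 2)
    } else if (cm$directed) {
      from <- if (fij) i else j; to <- if (fij) j else i
      xs <- seq(node_coords[from, 1], node_coords[to, 1], length.out = 11)
      ys <- seq(node_coords[from, 2], node_coords[to, 2], length.out = 11)
      graphics::segments(xs[-11], ys[-11], xs[-1], ys[-1], col = grad)
    } else {
      graphics::segments(node_coords[i, 1], node_coords[i, 2],
                         node_coords[j, 1], node_coords[j, 2],
                         col = grDevices::adjustcolor("grey30", alpha.f = 0.7))
    }
  }
  graphics::text(node_coords[, 1], node_coords[, 2], cm$roi_names,
                 pos = 3, cex = 0.6)
  invisible(list(n_edges = n_edges, n_bidirectional = n_bi, sizes = sizes))
}
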