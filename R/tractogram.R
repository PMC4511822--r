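#' Tractogram container
#'
#' A list of streamlines, each an n x 3 matrix of points in mm, sharing the
#' spatial frame of a parcellation.
#'
#' @param streamlines list of numeric matrices (>= 2 points each, 3 columns).
#' @param space_id identifier tying the tractogram to a parcellation frame.
#' @return object of class `tractogram`.
#' @export
tractogram <- function(streamlines, space_id = "native") {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3) stop("streamline points must have 3 coordinates")
    if (nrow(s) < 2) stop("streamline with <2 points")
    if (any(!is.finite(s))) stop("streamline contains non-finite points")
    unname(s)
  })
  structure(list(streamlines = streamlines, space_id = space_id),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, 0L)
  cat(sprintf("<tractogram> %d streamlines, %d points total (space '%s')\n",
              length(x$streamlines), sum(np), x$space_id))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

# --- TrackVis .trk ---------------------------------------------------------
# Minimal v2 implementation: n_scalars = n_properties = 0, voxel_size (1,1,1)
# and identity vox-to-ras, so the stored "voxmm" coordinates coincide with mm.

TRK_HDR_SIZE <- 1000L

#' Write a tractogram as a TrackVis .trk file
#'
#' @param tract a [tractogram()].
#' @param path output path ending in `.trk`.
#' @return `path`, invisibly.
#' @export
write_trk <- function(tract, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TRACK"), con); writeBin(raw(1), con)          # id_string
  writeBin(as.integer(c(0, 0, 0)), con, size = 2)                  # dim
  writeBin(c(1, 1, 1), con, size = 4)                              # voxel_size
  writeBin(c(0, 0, 0), con, size = 4)                              # origin
  writeBin(0L, con, size = 2)                                      # n_scalars
  writeBin(raw(200), con)                                          # scalar_name
  writeBin(0L, con, size = 2)                                      # n_properties
  writeBin(raw(200), con)                                          # property_name
  writeBin(as.numeric(t(diag(4))), con, size = 4)                  # vox_to_ras
  writeBin(raw(444), con)                                          # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)                       # voxel_order
  writeBin(raw(4), con)                                            # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4)                     # orientation
  writeBin(raw(2), con)                                            # pad1
  writeBin(raw(6), con)                                            # invert flags
  writeBin(length(tract$streamlines), con, size = 4)               # n_count
  writeBin(2L, con, size = 4)                                      # version
  writeBin(TRK_HDR_SIZE, con, size = 4)                            # hdr_size
  for (s in tract$streamlines) {
    writeBin(nrow(s), con, size = 4)
    writeBin(as.numeric(t(s)), con, size = 4)
  }
  invisible(path)
}

read_trk <- function(path, space_id = "native") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6)[1:5])
  if (magic != "TRACK") stop("malformed .trk header at byte 0: bad magic in ", path)
  seek(con, 988)
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != TRK_HDR_SIZE)
    stop("malformed .trk header at byte 996: hdr_size=", hdr_size)
  seek(con, 36)
  n_scalars <- readBin(con, "integer", 1, size = 2)
  seek(con, 238)
  n_properties <- readBin(con, "integer", 1, size = 2)
  seek(con, TRK_HDR_SIZE)
  out <- list()
  repeat {
    n <- readBin(con, "integer", 1, size = 4)
    if (!length(n)) break
    if (n < 2) stop("streamline with <2 points at byte ", seek(con, NA) - 4)
    pts <- readBin(con, "numeric", n * (3 + n_scalars), size = 4)
    if (length(pts) < n * (3 + n_scalars))
      stop("truncated .trk body at byte ", seek(con, NA))
    if (n_properties > 0) readBin(con, "numeric", n_properties, size = 4)
    m <- matrix(pts, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    out[[length(out) + 1]] <- m
    if (n_count > 0 && length(out) == n_count) break
  }
  tractogram(out, space_id = space_id)
}

# --- Plain-text fixture dialect -------------------------------------------
# One streamline per block of "x y z" lines; blank line separates blocks.

write_tract_text <- function(tract, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in tract$streamlines) {
    writeLines(apply(s, 1, function(p) paste(format(p, digits = 17), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

read_tract_text <- function(path, space_id = "native") {
  lines <- readLines(path)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  out <- list()
  lineno <- 0
  for (b in blocks) {
    pts <- trimws(b[nzchar(trimws(b))])
    lineno <- lineno + length(b)
    if (!length(pts)) next
    m <- tryCatch(
      do.call(rbind, lapply(strsplit(pts, "[ \t]+"), as.numeric)),
      warning = function(w) stop("malformed streamline block ending near line ",
                                 lineno, " in ", path))
    if (ncol(m) != 3) stop("expected 3 coordinates per line near line ", lineno)
    if (nrow(m) < 2) stop("streamline with <2 points near line ", lineno)
    out[[length(out) + 1]] <- m
  }
  tractogram(out, space_id = space_id)
}

#' Read a tractogram
#'
#' Dispatches on file extension: `.trk` files are parsed as TrackVis binary
#' streamline files; anything else is read as the plain-text fixture dialect
#' (one `x y z` line per point, blank line between streamlines). Coordinates
#' are returned in mm of the parcellation frame.
#'
#' @param path input path.
#' @param space_id spatial frame identifier recorded on the result.
#' @return a [tractogram()].
#' @export
read_tractogram <- function(path, space_id = "native") {
  if (grepl("\\.trk$", path, ignore.case = TRUE)) read_trk(path, space_id)
  else read_tract_text(path, space_id)
}

#' Write a tractogram
#'
#' Counterpart of [read_tractogram()]; format chosen by extension.
#'
#' @param tract a [tractogram()].
#' @param path output path (`.trk` for TrackVis binary, else text).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(tract, path) {
  if (grepl("\\.trk$", path, ignore.case = TRUE)) write_trk(tract, path)
  else write_tract_text(tract, path)
}
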