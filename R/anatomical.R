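#' Anatomical connectivity matrix from morphometric ratios
#'
#' Builds the a-CM for one morphometric measure: entry (i, j) is the ratio of
#' the measure between ROIs i and j. The default symmetric convention is
#' `min(m_i, m_j) / max(m_i, m_j)`, giving an undirected matrix with entries
#' in (0, 1]; `mode = "directional"` instead stores the raw ratio
#' `m_i / m_j` as a directed matrix. Cortical measures (CT, SA, GMV)
#' restrict the matrix to cortical ROIs; `volume` restricts it to
#' subcortical ROIs.
#'
#' @param morph morphometry data.frame (see [write_morphometry()]).
#' @param measure one of `"CT"`, `"SA"`, `"GMV"`, `"volume"`.
#' @param mode `"minmax"` (default, symmetric) or `"directional"`.
#' @return a [conn_matrix()] with modality `"a"` and ratio weights.
#' @export
anatomical_cm <- function(morph, measure = c("CT", "SA", "GMV", "volume"),
                          mode = c("minmax", "directional")) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  keep_class <- if (measure == "volume") "subcortical" else "cortical"
  rows <- morph[morph$tissue_class == keep_class, , drop = FALSE]
  if (!nrow(rows)) stop("no ", keep_class, " ROIs with measure ", measure)
  m <- rows[[measure]]
  bad <- which(!is.finite(m) | m <= 0)
  if (length(bad))
    stop("measure ", measure, " not positive for ROI(s): ",
         paste(rows$name[bad], collapse = ", "))
  if (mode == "minmax") {
    vals <- outer(m, m, pmin) / outer(m, m, pmax)
  } else {
    vals <- outer(m, m, `/`)
  }
  diag(vals) <- 0
  conn_matrix(vals, rows$label_id, modality = "a",
              directed = (mode == "directional"), weight_kind = "ratio",
              roi_names = rows$name)
}
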