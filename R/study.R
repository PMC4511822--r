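#' Discover a Study-Subject-Acquisition directory tree
#'
#' Studies are laid out as `<study>/<subject>/<acquisition>/<run>/...`.
#' Each immediate subdirectory of `root` is a subject; acquisition kinds are
#' inferred case-insensitively from subdirectory names (`smri`/`anat`/`t1`/
#' `amri` -> amri, `dti`/`dwi`/`dmri` -> dmri, `fmri`/`bold`/`rest` -> fmri,
#' `pet` -> pet), with run folders beneath. Subject and run listings are
#' sorted, so repeated calls return identical indexes.
#'
#' @param root study root directory.
#' @return object of class `study_index`: list with `study_root` and
#'   `subjects`, a named list mapping subject id to a named list of
#'   acquisition kind -> character vector of run paths.
#' @export
discover_study_tree <- function(root) {
  if (!dir.exists(root)) stop("study root does not exist: ", root)
  subj_dirs <- sort(list.dirs(root, recursive = FALSE))
  if (!length(subj_dirs)) stop("no subjects found in ", root)
  kinds <- list(amri = "^(smri|anat|t1w?|amri)$",
                dmri = "^(dti|dwi|dmri)$",
                fmri = "^(fmri|bold|rest(ing)?)$",
                pet  = "^pet$")
  subjects <- list()
  for (sd in subj_dirs) {
    sid <- basename(sd)
    acq_dirs <- sort(list.dirs(sd, recursive = FALSE))
    acqs <- list()
    for (ad in acq_dirs) {
      nm <- tolower(basename(ad))
      kind <- names(kinds)[vapply(kinds, function(p) grepl(p, nm), FALSE)]
      if (!length(kind)) next
      runs <- sort(list.dirs(ad, recursive = FALSE))
      if (!length(runs)) runs <- ad  # flat acquisition folder counts as one run
      acqs[[kind[1]]] <- c(acqs[[kind[1]]], runs)
    }
    if (!length(acqs))
      warning("subject '", sid, "' has no recognized acquisitions", call. = FALSE)
    subjects[[sid]] <- acqs
  }
  structure(list(study_root = root, subjects = subjects), class = "study_index")
}

#' @export
print.study_index <- function(x, ...) {
  cat(sprintf("<study_index> %s: %d subjects\n", x$study_root, length(x$subjects)))
  for (sid in names(x$subjects))
    cat(sprintf("  %s: %s\n", sid,
                if (length(x$subjects[[sid]]))
                  paste(names(x$subjects[[sid]]), collapse = ", ")
                else "(none)"))
  invisible(x)
}
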