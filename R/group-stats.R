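# Between-group statistics on per-ROI metrics and per-edge connectivity,
# with optional covariate regression before testing.

#' Split subjects into two groups
#'
#' @param covariates data.frame with one row per subject.
#' @param variable covariate name (e.g. `"age"`, `"sex"`, `"group"`).
#' @param rule either a numeric threshold (group 1: value < threshold,
#'   group 2: value >= threshold) or a label (group 1: equal, group 2: the
#'   rest).
#' @return list with integer index vectors `group1`, `group2`.
#' @export
split_groups <- function(covariates, variable, rule) {
  if (!variable %in% names(covariates))
    stop("covariate '", variable, "' not present")
  v <- covariates[[variable]]
  if (is.numeric(rule) && is.numeric(v)) g1 <- v < rule
  else g1 <- v == rule
  if (!any(g1) || all(g1)) stop("split produces an empty group")
  list(group1 = which(g1), group2 = which(!g1))
}

#' Residualize values on covariates
#'
#' Ordinary least-squares residuals of a per-subject vector on a covariate
#' design (plus intercept). Residuals sum to zero.
#'
#' @param values numeric vector, one entry per subject.
#' @param covariates data.frame of regressors (factors allowed).
#' @return residual vector.
#' @export
regress_covariates <- function(values, covariates) {
  df <- as.data.frame(covariates)
  if (length(values) <= ncol(df) + 1)
    stop("need more subjects than covariates")
  X <- stats::model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  stats::residuals(stats::lm.fit(X, values))
}

#' Between-group tests over a family of targets
#'
#' Welch two-sample t-tests (pooled-variance mode available) per target
#' column, after optional residualization on covariates; the direction is
#' the sign of the group-2 minus group-1 mean (`increase`/`decrease`),
#' matching the red/blue encoding of the connectogram. Significance is
#' assessed after the selected multiplicity correction over the target
#' family. Targets with zero variance in both groups are skipped with a
#' warning.
#'
#' @param values_a,values_b numeric matrices (subjects x targets) for the
#'   two groups; column names identify the targets (ROI metrics or edges).
#' @param covariates_a,covariates_b optional per-group covariate
#'   data.frames, residualized out before testing.
#' @param correction `"none"` (default), `"bonferroni"` or `"fdr_bh"`.
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame with one row per target: `target`, `t`, `p`,
#'   `p_adjusted`, `direction`, `significant`; attributes record the method
#'   metadata.
#' @export
groupwise_test <- function(values_a, values_b, covariates_a = NULL,
                           covariates_b = NULL,
                           correction = c("none", "bonferroni", "fdr_bh"),
                           alpha = 0.05, var_equal = FALSE) {
  correction <- match.arg(correction)
  values_a <- as.matrix(values_a); values_b <- as.matrix(values_b)
  if (ncol(values_a) != ncol(values_b)) stop("target families differ")
  if (nrow(values_a) < 2 || nrow(values_b) < 2)
    stop("each group needs at least 2 subjects")
  targets <- colnames(values_a)
  if (is.null(targets)) targets <- paste0("target", seq_len(ncol(values_a)))
  if (!is.null(covariates_a) || !is.null(covariates_b)) {
    cov_all <- rbind(as.data.frame(covariates_a), as.data.frame(covariates_b))
    na <- nrow(values_a)
    for (j in seq_len(ncol(values_a))) {
      res <- regress_covariates(c(values_a[, j], values_b[, j]), cov_all)
      values_a[, j] <- res[seq_len(na)]
      values_b[, j] <- res[-seq_len(na)]
    }
  }
  tt <- pp <- rep(NA_real_, length(targets))
  for (j in seq_along(targets)) {
    va <- values_a[, j]; vb <- values_b[, j]
    if (stats::var(va) == 0 && stats::var(vb) == 0) {
      warning("target '", targets[j], "' has zero variance in both groups; skipped",
              call. = FALSE)
      next
    }
    ht <- stats::t.test(vb, va, var.equal = var_equal)
    tt[j] <- unname(ht$statistic)
    pp[j] <- ht$p.value
  }
  p_adj <- switch(correction,
                  none = pp,
                  bonferroni = stats::p.adjust(pp, "bonferroni"),
                  fdr_bh = stats::p.adjust(pp, "BH"))
  dirn <- ifelse(colMeans(values_b) - colMeans(values_a) >= 0,
                 "increase", "decrease")
  out <- data.frame(target = targets, t = tt, p = pp, p_adjusted = p_adj,
                    direction = dirn,
                    significant = !is.na(p_adj) & p_adj < alpha)
  attr(out, "method") <- list(test = if (var_equal) "pooled t" else "Welch t",
                              alpha = alpha, correction = correction,
                              regressed = !is.null(covariates_a) ||
                                !is.null(covariates_b))
  out
}
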