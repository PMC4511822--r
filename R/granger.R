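# Pairwise time-domain Granger causality.
#
# For direction x -> y at order p: the restricted model regresses y_t on an
# intercept and y_{t-1..t-p}; the full model adds x_{t-1..t-p}. The GC
# strength is the log ratio of residual sums of squares, and the F statistic
# ((RSS_r - RSS_f)/p) / (RSS_f/(T_eff - 2p - 1)) with T_eff = T - p usable
# rows is referred to F(p, T_eff - 2p - 1).

lagmat <- function(v, p) {
  Tn <- length(v)
  out <- matrix(0, Tn - p, p)
  for (k in seq_len(p)) out[, k] <- v[(p - k + 1):(Tn - k)]
  out
}

gc_one_direction <- function(x, y, p) {
  Tn <- length(y)
  yt <- y[(p + 1):Tn]
  Xr <- cbind(1, lagmat(y, p))
  Xf <- cbind(Xr, lagmat(x, p))
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf))
    stop("collinear or constant regressors in Granger fit")
  rss_r <- sum(qr.resid(qr(Xr), yt)^2)
  rss_f <- sum(qr.resid(qf, yt)^2)
  T_eff <- Tn - p
  df2 <- T_eff - 2 * p - 1
  eps <- .Machine$double.eps * max(1, rss_r)
  gc <- log(max(rss_r, eps) / max(rss_f, eps))
  F <- ((rss_r - rss_f) / p) / (max(rss_f, eps) / df2)
  pval <- stats::pf(F, p, df2, lower.tail = FALSE)
  c(gc = max(gc, 0), F = F, p = pval)
}

#' Granger causality between two series
#'
#' Tests both directions of a pair with the time-domain pairwise Granger
#' formulation. A noiseless deterministic coupling drives the full-model
#' residual to zero and yields a very large (but finite) GC value; this is
#' flagged with a warning, not an error.
#'
#' @param x,y numeric series of equal length T > 2*order + 2.
#' @param order autoregressive order (default 1).
#' @return data.frame with rows `x->y` and `y->x` and columns `gc`
#'   (log variance ratio), `F`, `p`.
#' @export
granger_pair <- function(x, y, order = 1) {
  p <- as.integer(order)
  Tn <- length(x)
  if (length(y) != Tn) stop("series lengths differ")
  if (Tn <= 2 * p + 2) stop("series too short for order ", p)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in series")
  xy <- gc_one_direction(x, y, p)
  yx <- gc_one_direction(y, x, p)
  if (xy[["gc"]] > 20 || yx[["gc"]] > 20)
    warning("near-deterministic coupling: full-model residual close to zero",
            call. = FALSE)
  out <- rbind(`x->y` = xy, `y->x` = yx)
  as.data.frame(out)
}

#' Effective connectivity matrix via pairwise Granger causality
#'
#' Runs [granger_pair()] over all ordered ROI pairs. Entry (i, j) of the GC
#' matrix is the strength of i -> j. The binary e-CM thresholds the p-values
#' at `alpha` divided by the ordered-pair family size R(R-1); edges
#' surviving in both directions are reported as bidirectional.
#'
#' @param signals a [roi_signals()].
#' @param order autoregressive order (default 1).
#' @param alpha significance level (default 0.05).
#' @return object of class `gc_result`: list with `gc` (directed
#'   [conn_matrix()]), `f`, `p` (matrices), `binary` (directed binary
#'   [conn_matrix()]), `bidirectional` (symmetric logical matrix),
#'   `alpha_effective`, `order`.
#' @export
effective_cm <- function(signals, order = 1, alpha = 0.05) {
  x <- signals$values
  R <- nrow(x)
  if (R < 2) stop("need at least 2 ROIs")
  gc <- f <- matrix(0, R, R)
  p <- matrix(1, R, R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    res <- granger_pair(x[i, ], x[j, ], order = order)
    gc[i, j] <- res$gc[1]; f[i, j] <- res$F[1]; p[i, j] <- res$p[1]
    gc[j, i] <- res$gc[2]; f[j, i] <- res$F[2]; p[j, i] <- res$p[2]
  }
  alpha_eff <- alpha / (R * (R - 1))
  bin <- (p < alpha_eff) * 1
  diag(bin) <- 0
  structure(list(
    gc = conn_matrix(gc, signals$roi_ids, modality = "e", directed = TRUE,
                     weight_kind = "gc", roi_names = signals$roi_names),
    f = f, p = p,
    binary = conn_matrix(bin, signals$roi_ids, modality = "e", directed = TRUE,
                         weight_kind = "binary", roi_names = signals$roi_names),
    bidirectional = bin == 1 & t(bin) == 1,
    alpha_effective = alpha_eff, order = order), class = "gc_result")
}
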