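#' Two-sided p-value from a t statistic
#'
#' `2 * P(T >= |t|)` under Student's t with `df` degrees of freedom, which
#' may be non-integer (Welch–Satterthwaite or penalized-regression effective
#' degrees of freedom).
#'
#' @param t statistic (vectorised).
#' @param df degrees of freedom, `> 0` (scalar or vector).
#' @return two-sided probability in `[0, 1]`.
#' @export
two_sided_p_from_t <- function(t, df) {
  if (any(!is.finite(df)) || any(df <= 0)) stop("'df' must be positive")
  2 * pt(abs(t), df = df, lower.tail = FALSE)
}

#' One-sample t test with Cohen's d
#'
#' Standard one-sample t test of mean `mu`, reported with the one-sample
#' Cohen's d `d = t / sqrt(n) = (mean - mu) / sd` and its normal-approximation
#' confidence interval. This is the test applied to spatially matched
#' difference scores (null: no deviation from the control reference).
#'
#' @param values numeric vector, `n >= 2`, non-constant.
#' @param mu null-hypothesis mean.
#' @param conf_level confidence level for the d interval.
#' @return object of class `penumbra_test`: list with `t`, `df`, `p`, `d`,
#'   `ci` (for d), `n`, `estimate`.
#' @export
one_sample_test <- function(values, mu = 0, conf_level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values")
  s <- sd(values)
  if (s == 0) stop("zero variance: t statistic undefined")
  m <- mean(values)
  t <- (m - mu) / (s / sqrt(n))
  d <- t / sqrt(n)
  structure(list(t = t, df = n - 1, p = two_sided_p_from_t(t, n - 1),
                 d = d, ci = d_confidence_interval(d, n, conf_level),
                 n = n, estimate = m),
            class = "penumbra_test")
}

#' @export
print.penumbra_test <- function(x, ...) {
  cat(sprintf("t(%.4g) = %.3f, p = %.4g", x$df, x$t, x$p))
  if (!is.null(x$d))
    cat(sprintf(", d = %.3f [%.3f, %.3f]", x$d, x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' One-sample Cohen's d from a t statistic
#'
#' @param t one-sample t statistic.
#' @param n sample size, `>= 2`.
#' @return `d = t / sqrt(n)`.
#' @export
cohens_d_one_sample <- function(t, n) {
  if (any(n < 2)) stop("'n' must be >= 2")
  t / sqrt(n)
}

#' Normal-approximation confidence interval for a one-sample Cohen's d
#'
#' `d +/- z * sqrt(1/n + d^2 / (2n))`, the large-sample standard error of a
#' standardized mean difference.
#'
#' @param d effect size.
#' @param n sample size.
#' @param level confidence level.
#' @return numeric length-2 vector `(lower, upper)`.
#' @export
d_confidence_interval <- function(d, n, level = 0.95) {
  if (n < 2) stop("'n' must be >= 2")
  se <- sqrt(1 / n + d^2 / (2 * n))
  z <- qnorm((1 + level) / 2)
  c(d - z * se, d + z * se)
}

#' Two-sample t test (Welch or pooled)
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @param var_equal `FALSE` for Welch–Satterthwaite df (default), `TRUE` for
#'   the pooled-variance test with `df = n1 + n2 - 2`.
#' @param conf_level confidence level for the d interval.
#' @return `penumbra_test` list; `d` is the standardized mean difference from
#'   the pooled SD, `estimate` is `mean(b) - mean(a)`.
#' @export
welch_two_sample_test <- function(a, b, var_equal = FALSE, conf_level = 0.95) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 finite values")
  v1 <- var(a); v2 <- var(b)
  if (v1 == 0 && v2 == 0) stop("zero variance in both samples")
  delta <- mean(b) - mean(a)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    t <- delta / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- if (sp > 0) delta / sp else NA_real_
  nh <- 2 / (1 / n1 + 1 / n2)   # harmonic-mean n for the d interval
  ci <- if (is.finite(d)) d_confidence_interval(d, nh, conf_level)
        else c(NA_real_, NA_real_)
  structure(list(t = t, df = df, p = two_sided_p_from_t(t, df), d = d,
                 ci = ci, n = c(n1, n2), estimate = delta),
            class = "penumbra_test")
}

#' Pearson correlation test
#'
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2`.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return list with `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- max(-1, min(1, r))
  df <- n - 2
  t <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- if (is.infinite(t)) 0 else two_sided_p_from_t(t, df)
  list(r = r, t = t, df = df, p = p, n = n)
}

#' Partial R-squared from a t statistic
#'
#' `t^2 / (t^2 + df)`: the share of residual outcome variance attributable to
#' one predictor, the effect size reported alongside (penalized) regression
#' t statistics.
#'
#' @param t statistic (vectorised).
#' @param df residual (possibly effective, non-integer) degrees of freedom.
#' @return value in `[0, 1)`.
#' @export
partial_r2 <- function(t, df) {
  if (any(df <= 0)) stop("'df' must be positive")
  t^2 / (t^2 + df)
}

#' Benjamini–Hochberg step-up significance mask
#'
#' Rejects the `k0` smallest p-values where `k0` is the largest `k` with
#' `p_(k) <= k * alpha / m`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (NAs not rejected).
#' @param alpha target false discovery rate.
#' @return logical vector of rejections, same length as `pvalues`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0L) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- logical(m)
  ok <- which(is.finite(pvalues))
  if (!length(ok)) return(out)
  p <- pvalues[ok]
  mm <- length(p)
  o <- order(p)
  passes <- p[o] <= seq_len(mm) * alpha / mm
  k0 <- if (any(passes)) max(which(passes)) else 0L
  if (k0 > 0L) out[ok[o[seq_len(k0)]]] <- TRUE
  out
}

#' Voxelwise group comparison with FDR and cluster extent thresholding
#'
#' Fits, at every in-mask voxel, the linear model `value ~ group (+ covariates)`
#' across subjects and tests the group contrast, then applies
#' Benjamini–Hochberg FDR over the in-mask voxels at level `alpha` and
#' removes significant connected components smaller than `extent_k` voxels.
#' Voxels with zero residual variance are excluded from the test and from
#' the FDR family (their count is returned).
#'
#' @param maps list of subject [volume_map()]s (or 3D arrays) on one grid.
#' @param group factor or 0/1 vector, one entry per subject, two levels;
#'   the contrast is level 2 minus level 1.
#' @param analysis_mask non-empty logical 3D array.
#' @param covariates optional numeric matrix/data.frame of nuisance
#'   regressors (one row per subject).
#' @param alpha FDR level.
#' @param extent_k minimum cluster size in voxels.
#' @param connectivity 6 or 26 (see [label_components()]).
#' @param voxel_size_mm spacing for the returned statistic map.
#' @return list with `t_map` ([volume_map()], 0 outside mask),
#'   `significant` (logical array after FDR + extent), `clusters`
#'   (data.frame: label, size, peak_t, peak_x/y/z), `df`, `n_excluded`.
#' @export
voxelwise_group_glm <- function(maps, group, analysis_mask,
                                covariates = NULL, alpha = 0.05,
                                extent_k = 10, connectivity = 26,
                                voxel_size_mm = c(1, 1, 1)) {
  mask <- as_mask_array(analysis_mask, "analysis_mask")
  if (!any(mask)) stop("'analysis_mask' is empty")
  arrs <- lapply(maps, as_vol_array)
  for (a in arrs) check_same_grid(mask, a, "analysis_mask", "map")
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(group)
  if (length(unique(g)) != 2L) stop("'group' must have exactly two levels")
  if (min(table(g)) < 2L) stop("need >= 2 subjects per group")
  n <- length(arrs)
  if (length(g) != n) stop("'group' length must match number of maps")
  idx <- which(mask)
  Y <- vapply(arrs, function(a) a[idx], numeric(length(idx)))
  Y <- t(Y)                                     # subjects x voxels
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("'covariates' rows must match subjects")
    X <- cbind(X, covariates)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient voxelwise design matrix")
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  df <- n - p
  s2 <- colSums(res^2) / df
  se <- sqrt(pmax(s2, 0) * XtXi[2, 2])
  tv <- as.numeric(B[2, ]) / se
  testable <- s2 > .Machine$double.eps * max(s2, 1)
  n_excluded <- sum(!testable)
  pv <- rep(NA_real_, length(tv))
  pv[testable] <- two_sided_p_from_t(tv[testable], df)
  sig <- bh_fdr(pv[testable], alpha)
  sig_full <- logical(length(tv))
  sig_full[testable] <- sig
  sig_arr <- array(FALSE, dim(mask))
  sig_arr[idx] <- sig_full
  lab <- label_components(sig_arr, connectivity)
  clusters <- data.frame(label = integer(0), size = integer(0),
                         peak_t = numeric(0), peak_x = integer(0),
                         peak_y = integer(0), peak_z = integer(0))
  t_arr <- array(0, dim(mask))
  t_arr[idx] <- ifelse(testable, tv, 0)
  if (max(lab) > 0) {
    keep <- integer(0)
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l)
      if (length(vox) < extent_k) {
        sig_arr[vox] <- FALSE
        next
      }
      keep <- c(keep, l)
      pk <- vox[which.max(abs(t_arr[vox]))]
      co <- arrayInd(pk, dim(mask))
      clusters <- rbind(clusters, data.frame(
        label = l, size = length(vox), peak_t = t_arr[pk],
        peak_x = co[1], peak_y = co[2], peak_z = co[3]))
    }
    if (nrow(clusters))
      clusters <- clusters[order(-clusters$size), , drop = FALSE]
  }
  list(t_map = volume_map(t_arr, voxel_size_mm, units = "t"),
       significant = sig_arr, clusters = clusters, df = df,
       n_excluded = n_excluded)
}
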