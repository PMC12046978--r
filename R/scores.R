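#' Control-group voxelwise reference atlas
#'
#' Voxelwise arithmetic mean of the control subjects' metric maps. The atlas
#' is the spatial reference against which case difference scores are computed:
#' holding the anatomical location fixed removes the region-dependent
#' variation in normal myelination that would otherwise confound comparisons
#' across subjects with differently located lesions.
#'
#' @param control_maps non-empty list of [volume_map()]s (or 3D arrays) on a
#'   shared grid.
#' @return object of class `reference_atlas`: list with `mean` (3D array),
#'   `n_controls`, `voxel_size_mm`.
#' @export
cn_reference_map <- function(control_maps) {
  if (!is.list(control_maps) || length(control_maps) == 0L)
    stop("'control_maps' must be a non-empty list")
  sp <- c(1, 1, 1)
  if (inherits(control_maps[[1]], "volume_map"))
    sp <- control_maps[[1]]$voxel_size_mm
  arrs <- lapply(control_maps, as_vol_array)
  for (a in arrs) check_same_grid(arrs[[1]], a, "control_maps[[1]]", "map")
  m <- Reduce(`+`, arrs) / length(arrs)
  structure(list(mean = m, n_controls = length(arrs), voxel_size_mm = sp),
            class = "reference_atlas")
}

#' Spatially matched ROI difference score
#'
#' `raw` is the subject's mean over the ROI, `reference` the control-group
#' mean map averaged over the *same* subject-specific ROI, and
#' `diff = raw - reference`; a negative difference means the subject lies
#' below the control average in that location.
#'
#' @param subject_map [volume_map()] or 3D array.
#' @param roi_mask non-empty logical 3D array (e.g. the subject's WMH mask or
#'   a penumbra ring).
#' @param atlas [cn_reference_map()] result (or a 3D array of reference
#'   means).
#' @return list with `raw_value`, `reference_value`, `diff`, `n_voxels`.
#' @export
roi_difference_score <- function(subject_map, roi_mask, atlas) {
  sm <- as_vol_array(subject_map, "subject_map")
  roi <- as_mask_array(roi_mask, "roi_mask")
  ref <- if (inherits(atlas, "reference_atlas")) atlas$mean
         else as_vol_array(atlas, "atlas")
  check_same_grid(sm, roi, "subject_map", "roi_mask")
  check_same_grid(sm, ref, "subject_map", "atlas")
  if (!any(roi)) stop("empty ROI: no voxels to average")
  raw <- mean(sm[roi])
  rv <- mean(ref[roi])
  list(raw_value = raw, reference_value = rv, diff = raw - rv,
       n_voxels = sum(roi))
}

#' Covariate-adjusted difference scores
#'
#' Fits an ordinary least squares model of the raw case-group ROI values on
#' the covariates, then forms, for each case `i`,
#' `adjusted_diff_i = (prediction at the case-group mean covariate vector
#' + residual_i) - reference_i`. Because the OLS prediction at the covariate
#' mean equals the mean raw value, the case-group mean of
#' `adjusted_diff + reference` equals the mean raw value exactly (covariate
#' adjustment redistributes individual deviations but preserves the group
#' effect).
#'
#' @param values numeric vector of raw per-case ROI values.
#' @param covariates data.frame or matrix of complete numeric covariates
#'   (one row per case); categorical covariates must already be coded
#'   numerically (e.g. sex as 0/1).
#' @param references per-case reference values (the spatially matched
#'   control means).
#' @return numeric vector of adjusted difference scores, with the fitted
#'   model in attribute `"fit"`.
#' @export
adjusted_difference_scores <- function(values, covariates, references) {
  values <- as.numeric(values)
  n <- length(values)
  cov_m <- as.matrix(as.data.frame(covariates))
  if (ncol(cov_m) == 0L) cov_m <- matrix(numeric(0), nrow = n, ncol = 0)
  if (!is.numeric(cov_m)) stop("covariates must be numeric")
  if (nrow(cov_m) != n || length(references) != n)
    stop("'values', 'covariates' and 'references' must have one row per case")
  if (anyNA(values) || anyNA(cov_m) || anyNA(references))
    stop("missing entries are not allowed")
  p <- ncol(cov_m)
  if (n <= p + 1)
    stop(sprintf("n = %d cases cannot support %d covariates (need n > p + 1)", n, p))
  X <- cbind(`(Intercept)` = 1, cov_m)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qrX, values)
  fitted <- drop(X %*% beta)
  res <- values - fitted
  pred_at_mean <- drop(c(1, colMeans(cov_m)) %*% beta)  # == mean(values)
  out <- pred_at_mean + res - as.numeric(references)
  attr(out, "fit") <- list(coefficients = beta, pred_at_mean = pred_at_mean)
  out
}
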