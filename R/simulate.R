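# Seeded synthetic cohort generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes, not MR physics: two groups on one shared voxel grid, group-
# dependent periventricular lesion burden, additive lesion effects on each
# metric that decay exponentially with Euclidean distance from the lesion
# boundary, subject-level random intercepts plus voxel noise, and a cognition
# outcome linearly coupled to the planted lesion myelin deficit.

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  invisible(NULL)
}

#' Default per-metric simulation parameters
#'
#' One row per metric: baseline spatial mean, voxel noise SD, per-group
#' between-subject intercept SDs, the additive lesion effect inside the WMH
#' (on the stored physical scale) and the unit label. The chi-negative
#' defaults tie the planted WMH effect to the case between-subject SD so the
#' population one-sample effect size of the WMH difference score is
#' `-0.010 / 0.004 = -2.5`.
#'
#' @return data.frame with columns `metric`, `baseline_mean`, `voxel_sd`,
#'   `subject_sd_case`, `subject_sd_control`, `lesion_effect`, `units`.
#' @export
default_metric_params <- function() {
  # Physical-scale baselines (chi maps in ppm, diffusivities in mm^2/s,
  # free water unitless). chi_neg is stored as a diamagnetic (negative)
  # susceptibility; its analysis scale is the magnitude |chi_neg|.
  # subject_sd_* are the between-subject random-intercept SDs; controls are a
  # screened, matched group and carry far less between-subject spread than
  # the disease group, whose intercept reflects heterogeneous disease
  # severity.
  data.frame(
    metric = c("chi_neg", "chi_pos", "md", "rd", "fw"),
    baseline_mean = c(-0.045, 0.035, 8.0e-4, 6.0e-4, 0.15),
    voxel_sd = c(0.010, 0.010, 1.2e-4, 1.2e-4, 0.05),
    subject_sd_case = c(0.004, 0.003, 4.0e-5, 4.0e-5, 0.015),
    subject_sd_control = c(0.0008, 0.0006, 8.0e-6, 8.0e-6, 0.003),
    lesion_effect = c(+0.010, -0.006, +3.0e-4, +2.5e-4, +0.25),
    units = c("ppm", "ppm", "mm^2/s", "mm^2/s", ""),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a desk-scale analogue of a lesioned-brain cohort:
#' 60 cases vs 20 controls on a 48 x 56 x 48 grid at 2 mm isotropic spacing,
#' case lesion burden around 6% of brain volume vs 0.2% in controls, a
#' chi-negative lesion effect whose magnitude over the between-subject SD
#' gives a planted one-sample effect size of d = -2.5 on the difference-score
#' scale, and a boundary-distance exponential penumbra decay with a 2.6 mm
#' e-folding length chosen by power analysis so the planted gradient stays
#' detectable to roughly 6 mm (ring 3) but not beyond at n = 60.
#'
#' @param grid_shape voxel counts per axis (length 3).
#' @param voxel_size_mm per-axis spacing in mm.
#' @param n_case,n_control group sizes (`> 0`).
#' @param wmh_volume_fraction named vector `c(case=, control=)`: mean lesion
#'   volume as a fraction of brain volume, each in `(0, 0.5)`.
#' @param wmh_fraction_cv_log log-scale SD of the per-subject lesion burden
#'   (lognormal variation around the group mean).
#' @param lacune_count_mean named vector `c(case=, control=)`: Poisson means.
#' @param metric_params data.frame as [default_metric_params()]: per metric
#'   the spatial baseline mean, voxel noise SD, per-group subject-intercept
#'   SDs and the additive lesion effect inside the WMH.
#' @param metrics subset of metrics to simulate (default all five).
#' @param penumbra_decay_mm e-folding length in mm of the lesion effect
#'   beyond the WMH boundary (`>= 0`; 0 means no penumbra).
#' @param cognition_coefficients named vector of linear weights
#'   (`myelin`, `age`, `sex`, `education`) on standardized predictor scales;
#'   `myelin` multiplies the subject's planted WMH chi-negative deficit in
#'   units of the case between-subject SD.
#' @param cognition_noise_sd SD of the Gaussian outcome noise.
#' @param ring_step_mm,ring_max_mm penumbra ring geometry.
#' @param seed integer seed; the cohort is bit-reproducible given the config.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(grid_shape = c(48, 56, 48),
                              voxel_size_mm = c(2, 2, 2),
                              n_case = 60, n_control = 20,
                              wmh_volume_fraction = c(case = 0.06,
                                                      control = 0.002),
                              wmh_fraction_cv_log = 0.5,
                              lacune_count_mean = c(case = 4.7,
                                                    control = 0.05),
                              metric_params = default_metric_params(),
                              metrics = metric_params$metric,
                              penumbra_decay_mm = 2.6,
                              cognition_coefficients = c(myelin = 0.5,
                                                         age = -0.1,
                                                         sex = 0,
                                                         education = 0.15),
                              cognition_noise_sd = 0.8,
                              ring_step_mm = 2, ring_max_mm = 10,
                              seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("'grid_shape' must be 3 voxel counts >= 8")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (any(voxel_size_mm <= 0)) stop("'voxel_size_mm' must be positive")
  if (n_case <= 0 || n_control <= 0) stop("group sizes must be > 0")
  wmh_volume_fraction <- wmh_volume_fraction[c("case", "control")]
  if (anyNA(wmh_volume_fraction) ||
      any(wmh_volume_fraction <= 0 | wmh_volume_fraction >= 0.5))
    stop("'wmh_volume_fraction' must name case and control values in (0, 0.5)")
  if (penumbra_decay_mm < 0) stop("'penumbra_decay_mm' must be >= 0")
  if (any(lacune_count_mean < 0)) stop("'lacune_count_mean' must be >= 0")
  metrics <- match.arg(metrics, metric_params$metric, several.ok = TRUE)
  missing_w <- setdiff(c("myelin", "age", "sex", "education"),
                       names(cognition_coefficients))
  if (length(missing_w))
    stop("'cognition_coefficients' lacks: ", paste(missing_w, collapse = ", "))
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 wmh_volume_fraction = wmh_volume_fraction,
                 wmh_fraction_cv_log = wmh_fraction_cv_log,
                 lacune_count_mean = lacune_count_mean,
                 metric_params = metric_params,
                 metrics = metrics,
                 penumbra_decay_mm = penumbra_decay_mm,
                 cognition_coefficients = cognition_coefficients,
                 cognition_noise_sd = cognition_noise_sd,
                 ring_step_mm = ring_step_mm, ring_max_mm = ring_max_mm,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Shared anatomy: ellipsoidal brain, ellipsoidal white matter core, two
# paraventricular cavities standing in for the lateral ventricles. Returns
# brain/wm masks, a smooth WM probability map, and the ventricle distance
# field used to seed periventricular lesions.
simulate_anatomy <- function(config) {
  dm <- config$grid_shape
  sp <- config$voxel_size_mm
  half <- (dm - 1) / 2
  ax <- lapply(1:3, function(i) ((seq_len(dm[i]) - 1) - half[i]) * sp[i])
  ell <- function(center_mm, semi_mm) {
    qx <- ((ax[[1]] - center_mm[1]) / semi_mm[1])^2
    qy <- ((ax[[2]] - center_mm[2]) / semi_mm[2])^2
    qz <- ((ax[[3]] - center_mm[3]) / semi_mm[3])^2
    outer(outer(qx, qy, `+`), qz, `+`) < 1
  }
  ext <- half * sp
  brain <- ell(c(0, 0, 0), 0.92 * ext)
  wm_core <- ell(c(0, 0, 0), 0.74 * ext)
  vent <- ell(c(-0.18 * ext[1], 0, 0.05 * ext[3]),
              c(0.10 * ext[1], 0.42 * ext[2], 0.16 * ext[3])) |
          ell(c(+0.18 * ext[1], 0, 0.05 * ext[3]),
              c(0.10 * ext[1], 0.42 * ext[2], 0.16 * ext[3]))
  wm <- wm_core & !ball_dilate(vent, max(sp), sp)
  wm_prob <- gaussian_smooth_3d(array(as.numeric(wm), dm), sigma_mm = 2.5,
                                voxel_size_mm = sp)
  wm_prob <- pmin(pmax(wm_prob, 0), 1)
  dim(wm_prob) <- dm
  # keep the analysis WM mask consistent with thresholding the probability
  wm <- wm_mask_from_probability(wm_prob, threshold = 0.5, erode_mm = 0)
  list(brain = brain, wm = wm, wm_prob = wm_prob, vent = vent,
       d_vent = distance_to_mask(vent, sp),
       lesion_kern_fft = gauss_kernel_fft(dm, sigma_mm = 6, sp))
}

# Grow one subject's WMH mask: threshold (a smooth random field minus a
# periventricular distance penalty) at the exact target voxel count.
grow_wmh <- function(anatomy, config, target_voxels) {
  dm <- config$grid_shape
  sp <- config$voxel_size_mm
  wm_idx <- which(anatomy$wm)
  if (target_voxels > 0.9 * length(wm_idx))
    stop(sprintf(
      "grid too small: requested WMH volume (%d voxels) exceeds 90%% of the white matter (%d voxels)",
      target_voxels, length(wm_idx)))
  noise <- array(rnorm(prod(dm)), dm)
  field <- gaussian_smooth_3d(noise, sigma_mm = 6, voxel_size_mm = sp,
                              kern_fft = anatomy$lesion_kern_fft)
  field <- field / sd(field)
  score <- 0.8 * field[wm_idx] - anatomy$d_vent[wm_idx] / 12
  out <- array(FALSE, dm)
  if (target_voxels > 0)
    out[wm_idx[order(score, decreasing = TRUE)[seq_len(target_voxels)]]] <- TRUE
  out
}

# Small cavities: one seed voxel plus its face neighbours, kept inside WM.
place_lacunes <- function(anatomy, config, count) {
  dm <- config$grid_shape
  out <- array(FALSE, dm)
  if (count <= 0) return(out)
  wm_idx <- which(anatomy$wm)
  centers <- arrayInd(sample(wm_idx, min(count, length(wm_idx))), dm)
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(centers))) {
    pts <- sweep(offs, 2, centers[r, ], `+`)
    ok <- pts[, 1] >= 1 & pts[, 1] <= dm[1] &
          pts[, 2] >= 1 & pts[, 2] <= dm[2] &
          pts[, 3] >= 1 & pts[, 3] <= dm[3]
    out[pts[ok, , drop = FALSE]] <- TRUE
  }
  out & anatomy$wm
}

#' Simulate a synthetic two-group cohort
#'
#' Generates `n_case + n_control` subjects on a shared grid (see
#' [simulation_config()]): per-subject WMH and lacune masks, metric maps with
#' planted lesion effects decaying as `effect * exp(-d / penumbra_decay_mm)`
#' with `d` the Euclidean distance to the WMH (full effect inside), subject
#' random intercepts, voxel noise, demographic covariates, and a cognition
#' outcome linearly coupled to the planted WMH myelin deficit. Deterministic
#' given the config (which includes the seed).
#'
#' @param config a [simulation_config()].
#' @return object of class `wmh_cohort`: list with `subjects` (list of
#'   `subject_record`: `id`, `group`, `age`, `sex` (0 = male, 1 = female),
#'   `education`, `maps` (named list of [volume_map()]), `masks`
#'   ([build_mask_set()]), `cognition`, `ground_truth`), `config`, and
#'   `anatomy` (shared masks).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  dm <- config$grid_shape
  sp <- config$voxel_size_mm
  anatomy <- simulate_anatomy(config)
  n_brain <- sum(anatomy$brain)
  mp <- config$metric_params[config$metric_params$metric %in% config$metrics, ,
                             drop = FALSE]
  groups <- c(rep("case", config$n_case), rep("control", config$n_control))
  n_all <- length(groups)
  # demographics loosely matched between groups
  age <- ifelse(groups == "case", rnorm(n_all, 54, 9), rnorm(n_all, 58, 10))
  sex <- rbinom(n_all, 1, ifelse(groups == "case", 0.62, 0.40))
  education <- pmax(8, round(ifelse(groups == "case", rnorm(n_all, 14.2, 2.2),
                                    rnorm(n_all, 15.4, 2.5))))
  tau_case <- setNames(mp$subject_sd_case, mp$metric)
  tau_ctrl <- setNames(mp$subject_sd_control, mp$metric)
  cw <- config$cognition_coefficients
  chi_row <- match("chi_neg", mp$metric)
  subjects <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    grp <- groups[i]
    base_frac <- config$wmh_volume_fraction[[grp]]
    frac <- base_frac * exp(rnorm(1, 0, config$wmh_fraction_cv_log))
    frac <- min(frac, 3 * base_frac)    # truncate the lognormal tail
    target <- max(1L, as.integer(round(frac * n_brain)))
    wmh <- grow_wmh(anatomy, config, target)
    n_lacunes <- rpois(1, config$lacune_count_mean[[grp]])
    lacunes <- place_lacunes(anatomy, config, n_lacunes)
    d_wmh <- distance_to_mask(wmh, sp)
    brain_idx <- which(anatomy$brain)
    decay_b <- if (config$penumbra_decay_mm > 0)
      exp(-d_wmh[brain_idx] / config$penumbra_decay_mm)
    else as.numeric(d_wmh[brain_idx] == 0)
    tau <- if (grp == "case") tau_case else tau_ctrl
    intercepts <- setNames(rnorm(nrow(mp), 0, tau[mp$metric]), mp$metric)
    maps <- vector("list", nrow(mp))
    names(maps) <- mp$metric
    for (j in seq_len(nrow(mp))) {
      v <- mp$baseline_mean[j] + intercepts[j] +
        mp$lesion_effect[j] * decay_b +
        rnorm(length(brain_idx), 0, mp$voxel_sd[j])
      v <- switch(mp$metric[j],
                  chi_neg = pmin(v, 0),
                  chi_pos = pmax(v, 0),
                  fw = pmin(pmax(v, 0), 1),
                  pmax(v, 1e-9))
      vals <- numeric(prod(dm))
      vals[brain_idx] <- v
      dim(vals) <- dm
      maps[[j]] <- volume_map(vals, sp, units = mp$units[j])
    }
    # planted WMH myelin deficit on the analysis (|chi_neg|) scale
    deficit <- if (!is.na(chi_row))
      -(mp$lesion_effect[chi_row] + intercepts[["chi_neg"]])
    else 0
    tau_ref <- if (!is.na(chi_row)) tau_case[["chi_neg"]] else 1
    cognition <- cw[["myelin"]] * deficit / tau_ref +
      cw[["age"]] * (age[i] - 55) / 8 +
      cw[["sex"]] * sex[i] +
      cw[["education"]] * (education[i] - 15) / 2.5 +
      rnorm(1, 0, config$cognition_noise_sd)
    nawm <- derive_nawm(anatomy$wm, wmh, lacunes)
    rings <- if (any(wmh))
      rings_from_distance(d_wmh, nawm, config$ring_step_mm,
                          config$ring_max_mm)
    else NULL
    masks <- new_mask_set(anatomy$wm, wmh, lacunes, nawm, rings, sp,
                          config$ring_step_mm, config$ring_max_mm)
    subjects[[i]] <- structure(
      list(id = sprintf("%s%03d", if (grp == "case") "case" else "ctrl", i),
           group = grp, age = age[i], sex = sex[i],
           education = education[i], maps = maps, masks = masks,
           cognition = cognition,
           lacune_count = n_lacunes,
           ground_truth = list(
             lesion_effects = setNames(mp$lesion_effect, mp$metric),
             intercepts = intercepts,
             wmh_deficit = deficit,
             wmh_fraction = sum(wmh) / n_brain,
             planted_d = if (!is.na(chi_row))
               -mp$lesion_effect[chi_row] / tau_case[["chi_neg"]]
             else NA_real_)),
      class = "subject_record")
  }
  structure(list(subjects = subjects, config = config, anatomy = anatomy),
            class = "wmh_cohort")
}

#' @export
print.wmh_cohort <- function(x, ...) {
  tb <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("<wmh_cohort> %d subjects (%s) on %s @ %s mm, seed %d\n",
              length(x$subjects),
              paste(names(tb), tb, sep = "=", collapse = ", "),
              paste(x$config$grid_shape, collapse = "x"),
              paste(x$config$voxel_size_mm, collapse = "x"),
              x$config$seed))
  invisible(x)
}

#' Subject table of a cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @return data.frame with id, group, age, sex, education, cognition,
#'   wmh_fraction (of brain volume), lacune_count.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "wmh_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) data.frame(
    id = s$id, group = s$group, age = s$age, sex = s$sex,
    education = s$education, cognition = s$cognition,
    wmh_fraction = if (!is.null(s$wmh_fraction)) s$wmh_fraction
                   else if (!is.null(s$ground_truth))
                     s$ground_truth$wmh_fraction
                   else NA_real_,
    lacune_count = if (!is.null(s$lacune_count)) s$lacune_count
                   else max(label_components(s$masks$lacunes, 26)),
    stringsAsFactors = FALSE)))
}
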