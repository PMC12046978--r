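# Pipeline orchestration: simulate/load -> masks -> reference atlas ->
# difference scores -> covariate adjustment -> penumbra gradient ->
# correlations -> ridge cognition models -> voxelwise mapping -> report.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

# Metrics are analysed on the scale on which "lower = worse myelin" holds:
# chi_neg maps are stored as diamagnetic (negative) susceptibility and
# analysed as the magnitude |chi_neg|; all other metrics are analysed as
# stored.
analysis_array <- function(map, metric) {
  v <- as_vol_array(map)
  if (metric == "chi_neg") -v else v
}

# Per-metric covariate sets for the difference-score adjustment: the myelin
# metric is adjusted for iron and free water, iron for free water, and the
# diffusion metrics for iron, each on top of the demographics.
adjustment_covariates <- function(metric, metrics) {
  extra <- switch(metric,
                  chi_neg = c("chi_pos", "fw"),
                  chi_pos = "fw",
                  c("chi_pos"))
  intersect(extra, setdiff(metrics, metric))
}

case_roi_masks <- function(subject, rois) {
  ms <- subject$masks
  out <- list()
  for (roi in rois) {
    out[[roi]] <- switch(roi,
      wmh = ms$wmh & !ms$lacunes,
      nawm = ms$nawm,
      {
        k <- as.integer(sub("^ring", "", roi))
        if (is.null(ms$rings)) array(FALSE, dim(ms$wm)) else ms$rings == k
      })
  }
  out
}

#' Compute difference scores, gradient tests, correlations and ridge models
#'
#' Runs the full statistical analysis of a cohort in memory: control
#' reference atlas per metric, per-case spatially matched difference scores
#' for the WMH, NAWM and penumbra-ring ROIs, covariate adjustment, one-sample
#' penumbra gradient tests with Cohen's d, pairwise metric correlations per
#' group, and ridge regressions of cognition on the per-ROI metric profiles
#' with effective-df inference. See [run_pipeline()] for the file-writing
#' wrapper.
#'
#' @param cohort a [simulate_cohort()] result (or an equivalent structure
#'   loaded from disk, see [read_cohort()]).
#' @param alpha significance level used in reports.
#' @param ridge_lambda `"auto"` (GCV, see [auto_lambda()]) or a fixed
#'   non-negative number.
#' @param voxelwise run the voxelwise group comparison of the myelin metric
#'   (can be disabled for speed).
#' @param extent_k,connectivity cluster extent threshold and connectivity of
#'   the voxelwise analysis.
#' @return list with `diff_scores` (long data.frame), `penumbra_table`,
#'   `correlations`, `ridge_models`, `ridge_fits`, `frequency_maps`,
#'   `voxelwise`, `subject_table`, `report`.
#' @export
analyze_cohort <- function(cohort, alpha = 0.05, ridge_lambda = "auto",
                           voxelwise = TRUE, extent_k = 10,
                           connectivity = 26) {
  stopifnot(inherits(cohort, "wmh_cohort"))
  cfg <- cohort$config
  sp <- cfg$voxel_size_mm
  metrics <- cfg$metrics
  subjects <- cohort$subjects
  groups <- vapply(subjects, `[[`, "", "group")
  cases <- subjects[groups == "case"]
  controls <- subjects[groups == "control"]
  if (length(controls) == 0L) stop("cohort has no controls")
  if (length(cases) == 0L) stop("cohort has no cases")
  k_rings <- as.integer(cfg$ring_max_mm / cfg$ring_step_mm)
  rois <- c("wmh", "nawm", paste0("ring", seq_len(k_rings)))

  atlas <- with_stage("reference_atlas", {
    lapply(setNames(metrics, metrics), function(m)
      cn_reference_map(lapply(controls, function(s)
        analysis_array(s$maps[[m]], m))))
  })

  diff_scores <- with_stage("difference_scores", {
    rows <- list()
    for (s in cases) {
      masks <- case_roi_masks(s, rois)
      for (roi in rois) {
        if (!any(masks[[roi]])) next   # subject contributes no such ROI
        for (m in metrics) {
          ds <- roi_difference_score(analysis_array(s$maps[[m]], m),
                                     masks[[roi]], atlas[[m]])
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = s$id, roi = roi, metric = m,
            raw = ds$raw_value, reference = ds$reference_value,
            diff = ds$diff, n_voxels = ds$n_voxels,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  subject_table <- cohort_table(cohort)

  diff_scores <- with_stage("covariate_adjustment", {
    demo <- subject_table[match(diff_scores$subject_id, subject_table$id), ]
    diff_scores$adjusted_diff <- NA_real_
    for (roi in unique(diff_scores$roi)) {
      sel_roi <- diff_scores$roi == roi
      for (m in metrics) {
        sel <- sel_roi & diff_scores$metric == m
        covs <- data.frame(age = demo$age[sel], sex = demo$sex[sel],
                           education = demo$education[sel])
        for (cm in adjustment_covariates(m, metrics))
          covs[[cm]] <- diff_scores$raw[sel_roi & diff_scores$metric == cm]
        if (nrow(covs) > ncol(covs) + 1) {
          diff_scores$adjusted_diff[sel] <- adjusted_difference_scores(
            diff_scores$raw[sel], covs, diff_scores$reference[sel])
        } else {
          diff_scores$adjusted_diff[sel] <- diff_scores$diff[sel]
        }
      }
    }
    diff_scores
  })

  penumbra_table <- with_stage("penumbra_gradient", {
    rows <- list()
    for (m in metrics) {
      for (roi in rois) {
        sel <- diff_scores$roi == roi & diff_scores$metric == m
        vals <- diff_scores$adjusted_diff[sel]
        if (sum(is.finite(vals)) < 3) next
        tst <- one_sample_test(vals, mu = 0)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, roi = roi, n = tst$n, estimate = tst$estimate,
          t = tst$t, df = tst$df, p = tst$p, d = tst$d,
          ci_lo = tst$ci[1], ci_hi = tst$ci[2], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  correlations <- with_stage("correlations", {
    rows <- list()
    pairs <- if (length(metrics) > 1) utils::combn(metrics, 2) else NULL
    add_rows <- function(group, roi, value_of) {
      if (is.null(pairs)) return()
      for (j in seq_len(ncol(pairs))) {
        m1 <- pairs[1, j]; m2 <- pairs[2, j]
        x <- value_of(m1); y <- value_of(m2)
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
        ct <- pearson_test(x[ok], y[ok])
        rows[[length(rows) + 1L]] <<- data.frame(
          group = group, roi = roi, metric_1 = m1, metric_2 = m2,
          r = ct$r, t = ct$t, df = ct$df, p = ct$p, n = ct$n,
          stringsAsFactors = FALSE)
      }
    }
    for (roi in c("nawm", "wmh"))
      add_rows("case", roi, function(m) {
        sel <- diff_scores$roi == roi & diff_scores$metric == m
        diff_scores$diff[sel]
      })
    # controls carry too few lesions for difference scores; use their plain
    # NAWM means
    ctrl_vals <- lapply(setNames(metrics, metrics), function(m)
      vapply(controls, function(s) {
        roi <- s$masks$nawm
        mean(analysis_array(s$maps[[m]], m)[roi])
      }, numeric(1)))
    add_rows("control", "nawm", function(m) ctrl_vals[[m]])
    do.call(rbind, rows)
  })

  ridge_out <- with_stage("ridge_models", {
    case_tab <- subject_table[subject_table$group == "case", ]
    outcome <- case_tab$cognition
    roi_pred <- function(roi) {
      sapply(setNames(metrics, metrics), function(m) {
        if (roi == "global_wm") {
          vapply(cases, function(s) {
            msk <- s$masks$wm & !s$masks$lacunes
            mean(analysis_array(s$maps[[m]], m)[msk])
          }, numeric(1))
        } else {
          sel <- diff_scores$roi == roi & diff_scores$metric == m
          diff_scores$diff[sel][match(case_tab$id,
                                      diff_scores$subject_id[sel])]
        }
      })
    }
    fits <- list()
    tab_rows <- list()
    for (roi in c("global_wm", "nawm", "wmh")) {
      X <- roi_pred(roi)
      X <- cbind(X, wmh_volume = case_tab$wmh_fraction,
                 age = case_tab$age, sex = case_tab$sex,
                 education = case_tab$education)
      ok <- stats::complete.cases(X) & is.finite(outcome)
      if (sum(ok) <= ncol(X) + 2) next
      lam <- if (identical(ridge_lambda, "auto"))
        as.numeric(auto_lambda(X[ok, , drop = FALSE], outcome[ok]))
      else as.numeric(ridge_lambda)
      fit <- ridge_fit(X[ok, , drop = FALSE], outcome[ok], lambda = lam)
      fits[[roi]] <- fit
      tab_rows[[roi]] <- data.frame(
        roi = roi, predictor = names(fit$coefficients),
        estimate_scaled = fit$coefficients, se_scaled = fit$se,
        t = fit$t, df = fit$edf, p = fit$p, partial_r2 = fit$partial_r2,
        r2 = fit$r2, lambda = fit$lambda, n = fit$n,
        row.names = NULL, stringsAsFactors = FALSE)
    }
    list(table = if (length(tab_rows))
           do.call(rbind, c(unname(tab_rows), list(make.row.names = FALSE)))
         else NULL,
         fits = fits)
  })

  frequency_maps <- with_stage("frequency_maps", {
    out <- list()
    for (grp in c("case", "control")) {
      subs <- subjects[groups == grp]
      out[[paste0("wmh_", grp)]] <-
        lesion_frequency_map(lapply(subs, function(s) s$masks$wmh), sp)
      out[[paste0("lacune_", grp)]] <-
        lesion_frequency_map(lapply(subs, function(s) s$masks$lacunes), sp)
    }
    out
  })

  vox <- NULL
  if (isTRUE(voxelwise) && "chi_neg" %in% metrics) {
    vox <- with_stage("voxelwise", {
      wm_any <- cohort$anatomy$wm
      voxelwise_group_glm(
        maps = lapply(subjects, function(s)
          analysis_array(s$maps$chi_neg, "chi_neg")),
        group = as.integer(groups == "case"),   # contrast: case - control
        analysis_mask = wm_any, alpha = alpha, extent_k = extent_k,
        connectivity = connectivity, voxel_size_mm = sp)
    })
  }

  report <- with_stage("cohort_report", cohort_report(subject_table))

  list(diff_scores = diff_scores, penumbra_table = penumbra_table,
       correlations = correlations, ridge_models = ridge_out$table,
       ridge_fits = ridge_out$fits, frequency_maps = frequency_maps,
       voxelwise = vox, subject_table = subject_table, report = report)
}

#' Demographics and group-comparison table
#'
#' Per-group mean and interquartile range for each numeric cohort variable,
#' with pooled-variance t tests (and Cohen's d from the pooled SD) for the
#' group comparison and a Pearson chi-square test for sex.
#'
#' @param subject_table data.frame with at least `group` plus any of `age`,
#'   `sex`, `education`, `cognition`, `wmh_fraction`, `lacune_count`.
#' @return data.frame with one row per variable.
#' @export
cohort_report <- function(subject_table) {
  need <- c("group")
  missing_cols <- setdiff(need, names(subject_table))
  if (length(missing_cols))
    stop("subject table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  grp <- subject_table$group
  if (!all(grp %in% c("case", "control")))
    stop("'group' must contain only 'case' and 'control'")
  num_vars <- intersect(c("age", "education", "cognition", "wmh_fraction",
                          "lacune_count"),
                        names(subject_table))
  rows <- list()
  for (v in num_vars) {
    x <- subject_table[[v]][grp == "control"]
    y <- subject_table[[v]][grp == "case"]
    tst <- tryCatch(welch_two_sample_test(x, y, var_equal = TRUE),
                    error = function(e) NULL)
    rows[[v]] <- data.frame(
      variable = v,
      control_mean = mean(x), control_iqr = unname(diff(quantile(x, c(.25, .75)))),
      case_mean = mean(y), case_iqr = unname(diff(quantile(y, c(.25, .75)))),
      statistic = if (is.null(tst)) NA_real_ else tst$t,
      df = if (is.null(tst)) NA_real_ else tst$df,
      p = if (is.null(tst)) NA_real_ else tst$p,
      d = if (is.null(tst)) NA_real_ else tst$d,
      test = "t", stringsAsFactors = FALSE)
  }
  if ("sex" %in% names(subject_table)) {
    tab <- table(factor(grp, c("control", "case")),
                 factor(subject_table$sex, c(0, 1)))
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
    rows[["sex"]] <- data.frame(
      variable = "sex_pct_female",
      control_mean = 100 * mean(subject_table$sex[grp == "control"]),
      control_iqr = NA_real_,
      case_mean = 100 * mean(subject_table$sex[grp == "case"]),
      case_iqr = NA_real_,
      statistic = unname(chi$statistic), df = unname(chi$parameter),
      p = chi$p.value, d = NA_real_, test = "chisq",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run configuration for the pipeline
#'
#' @param mode `"simulate"` (generate a cohort from `sim`) or `"load"` (read
#'   one written by [write_cohort()] from `cohort_dir`).
#' @param sim a [simulation_config()] (simulate mode).
#' @param cohort_dir directory with a written cohort (load mode).
#' @param out_dir output directory (created if missing); `NULL` disables all
#'   file output.
#' @param alpha,extent_k,connectivity,voxelwise,ridge_lambda see
#'   [analyze_cohort()].
#' @param write_volumes also write per-group frequency maps and the voxelwise
#'   statistic map as NIfTI.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       sim = simulation_config(), cohort_dir = NULL,
                       out_dir = NULL, alpha = 0.05, extent_k = 10,
                       connectivity = 26, voxelwise = TRUE,
                       ridge_lambda = "auto", write_volumes = TRUE) {
  mode <- match.arg(mode)
  if (mode == "load") {
    if (is.null(cohort_dir) || !dir.exists(cohort_dir))
      stop("load mode needs an existing 'cohort_dir'")
  } else stopifnot(inherits(sim, "simulation_config"))
  if (!identical(ridge_lambda, "auto") &&
      (!is.numeric(ridge_lambda) || ridge_lambda < 0))
    stop("'ridge_lambda' must be \"auto\" or a non-negative number")
  structure(list(mode = mode, sim = sim, cohort_dir = cohort_dir,
                 out_dir = out_dir, alpha = alpha, extent_k = extent_k,
                 connectivity = connectivity, voxelwise = voxelwise,
                 ridge_lambda = ridge_lambda, write_volumes = write_volumes),
            class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline and write the report bundle
#'
#' Simulates (or loads) a cohort, runs [analyze_cohort()], and writes the
#' report bundle to `out_dir`: per-group lesion frequency maps (NIfTI), the
#' long-format difference-score table, the penumbra gradient table, the
#' correlation table, the per-ROI ridge model tables, the voxelwise statistic
#' map and cluster table, the subject and demographics tables, and a
#' machine-readable JSON manifest (config, seed, package version). All
#' numbers in the bundle are recomputable from the manifest alone.
#'
#' @param config a [run_config()].
#' @return the [analyze_cohort()] result, with the cohort in `$cohort` and
#'   output paths in `$files`, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- with_stage(config$mode, {
    if (config$mode == "simulate") simulate_cohort(config$sim)
    else read_cohort(config$cohort_dir)
  })
  res <- analyze_cohort(cohort, alpha = config$alpha,
                        ridge_lambda = config$ridge_lambda,
                        voxelwise = config$voxelwise,
                        extent_k = config$extent_k,
                        connectivity = config$connectivity)
  res$cohort <- cohort
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    files <- c(files,
               write_tsv(res$subject_table, file.path(od, "cohort.tsv")),
               write_tsv(res$diff_scores, file.path(od, "diff_scores.tsv")),
               write_tsv(res$penumbra_table,
                         file.path(od, "penumbra_table.tsv")),
               write_tsv(res$correlations, file.path(od, "correlations.tsv")),
               write_tsv(res$report, file.path(od, "report.tsv")))
    if (!is.null(res$ridge_models))
      files <- c(files, write_tsv(res$ridge_models,
                                  file.path(od, "ridge_models.tsv")))
    if (!is.null(res$voxelwise))
      files <- c(files, write_tsv(res$voxelwise$clusters,
                                  file.path(od, "clusters.tsv")))
    if (isTRUE(config$write_volumes)) {
      for (nm in names(res$frequency_maps))
        files <- c(files, write_nifti(res$frequency_maps[[nm]],
                                      file.path(od, paste0("freq_", nm,
                                                           ".nii.gz"))))
      if (!is.null(res$voxelwise))
        files <- c(files, write_nifti(res$voxelwise$t_map,
                                      file.path(od, "chi_neg_tmap.nii.gz")))
    }
    manifest <- list(
      package_version = as.character(packageVersion("penumbra")),
      mode = config$mode,
      seed = if (config$mode == "simulate") config$sim$seed else NA,
      alpha = config$alpha, extent_k = config$extent_k,
      connectivity = config$connectivity,
      ridge_lambda = config$ridge_lambda,
      sim = if (config$mode == "simulate")
        config$sim[setdiff(names(config$sim), "metric_params")],
      metric_params = if (config$mode == "simulate")
        config$sim$metric_params)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    files <- c(files, file.path(od, "manifest.json"))
  }
  res$files <- files
  invisible(res)
}

#' Write / read a cohort as NIfTI volumes plus a subject TSV
#'
#' `write_cohort()` writes one NIfTI per subject and metric
#' (`<id>_<metric>.nii.gz`), the subject masks (`<id>_wmh.nii.gz`,
#' `<id>_lacunes.nii.gz`), the shared WM mask and probability map, the
#' subject table (`cohort.tsv`) and a small JSON manifest with the grid and
#' ring geometry. `read_cohort()` reconstructs a cohort object from such a
#' directory (without simulation ground truth).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir target/source directory.
#' @return the directory (write) or a `wmh_cohort` (read).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wmh_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- cohort$config$voxel_size_mm
  write_nifti(cohort$anatomy$wm, file.path(dir, "wm.nii.gz"), sp)
  write_nifti(volume_map(cohort$anatomy$wm_prob, sp),
              file.path(dir, "wm_prob.nii.gz"))
  for (s in cohort$subjects) {
    for (m in names(s$maps))
      write_nifti(s$maps[[m]], file.path(dir, sprintf("%s_%s.nii.gz",
                                                      s$id, m)))
    write_nifti(s$masks$wmh, file.path(dir, sprintf("%s_wmh.nii.gz", s$id)),
                sp)
    write_nifti(s$masks$lacunes,
                file.path(dir, sprintf("%s_lacunes.nii.gz", s$id)), sp)
  }
  write_tsv(cohort_table(cohort), file.path(dir, "cohort.tsv"))
  jsonlite::write_json(
    list(grid_shape = cohort$config$grid_shape,
         voxel_size_mm = sp, metrics = cohort$config$metrics,
         ring_step_mm = cohort$config$ring_step_mm,
         ring_max_mm = cohort$config$ring_max_mm,
         seed = cohort$config$seed),
    file.path(dir, "cohort_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "cohort_manifest.json")
  if (!file.exists(man_path)) stop("no cohort_manifest.json in ", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  tab <- read.delim(file.path(dir, "cohort.tsv"), stringsAsFactors = FALSE)
  sp <- as.numeric(man$voxel_size_mm)
  wm <- as_mask_array(read_nifti(file.path(dir, "wm.nii.gz"))$values, "wm")
  wm_prob <- read_nifti(file.path(dir, "wm_prob.nii.gz"))$values
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$id[i]
    maps <- lapply(setNames(man$metrics, man$metrics), function(m)
      read_nifti(file.path(dir, sprintf("%s_%s.nii.gz", id, m))))
    wmh <- as_mask_array(
      read_nifti(file.path(dir, sprintf("%s_wmh.nii.gz", id)))$values, "wmh")
    lac_path <- file.path(dir, sprintf("%s_lacunes.nii.gz", id))
    lac <- if (file.exists(lac_path))
      as_mask_array(read_nifti(lac_path)$values, "lacunes") else NULL
    structure(list(id = id, group = tab$group[i], age = tab$age[i],
                   sex = tab$sex[i], education = tab$education[i],
                   maps = maps,
                   masks = build_mask_set(wm, wmh, lac, sp,
                                          man$ring_step_mm, man$ring_max_mm),
                   cognition = tab$cognition[i],
                   wmh_fraction = tab$wmh_fraction[i],
                   lacune_count = tab$lacune_count[i],
                   ground_truth = NULL),
              class = "subject_record")
  })
  cfg <- simulation_config(grid_shape = man$grid_shape, voxel_size_mm = sp,
                           n_case = max(1, sum(tab$group == "case")),
                           n_control = max(1, sum(tab$group == "control")),
                           metrics = man$metrics,
                           ring_step_mm = man$ring_step_mm,
                           ring_max_mm = man$ring_max_mm,
                           seed = if (is.null(man$seed)) 0 else man$seed)
  structure(list(subjects = subjects, config = cfg,
                 anatomy = list(wm = wm, wm_prob = wm_prob)),
            class = "wmh_cohort")
}
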