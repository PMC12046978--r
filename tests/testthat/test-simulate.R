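test_that("cohorts are bit-reproducible given the seed", {
  cfg <- tiny_config(seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$subjects[[1]]$maps$chi_neg$values,
                   c2$subjects[[1]]$maps$chi_neg$values)
  expect_identical(c1$subjects[[3]]$masks$wmh, c2$subjects[[3]]$masks$wmh)
  expect_identical(cohort_table(c1), cohort_table(c2))
  c3 <- simulate_cohort(tiny_config(seed = 6))
  expect_false(identical(c1$subjects[[1]]$cognition,
                         c3$subjects[[1]]$cognition))
})

test_that("simulated subjects satisfy the domain invariants", {
  co <- simulate_cohort(tiny_config(seed = 8))
  brain <- co$anatomy$brain
  for (s in co$subjects[c(1, 2, 11)]) {
    ms <- s$masks
    expect_true(all(ms$wm[ms$wmh]))                # WMH inside WM
    expect_true(all(brain[ms$lacunes]))            # lacunes inside brain
    expect_false(any(ms$nawm & ms$wmh))
    expect_false(any(ms$nawm & ms$lacunes))
    for (m in names(s$maps))
      expect_true(all(is.finite(s$maps[[m]]$values[brain])))
    expect_true(all(s$maps$chi_neg$values <= 0))
    expect_true(all(s$maps$chi_pos$values >= 0))
    fw <- s$maps$fw$values
    expect_true(all(fw >= 0 & fw <= 1))
    expect_true(all(s$maps$md$values[brain] > 0))
    expect_true(all(s$maps$rd$values[brain] > 0))
  }
  # group-dependent lesion burden
  tab <- cohort_table(co)
  expect_gt(mean(tab$wmh_fraction[tab$group == "case"]), 0.02)
  expect_lt(mean(tab$wmh_fraction[tab$group == "control"]), 0.01)
})

test_that("planted ring shifts decay monotonically in magnitude", {
  co <- simulate_cohort(tiny_config(seed = 9))
  cfg <- co$config
  for (s in co$subjects[1:3]) {
    d <- distance_to_mask(s$masks$wmh, cfg$voxel_size_mm)
    shift_mean <- vapply(1:5, function(k)
      mean(exp(-d[s$masks$rings == k] / cfg$penumbra_decay_mm)), numeric(1))
    expect_true(all(diff(shift_mean) < 0))
  }
})

test_that("an impossible lesion volume fails with a clear message", {
  cfg <- tiny_config(seed = 2,
                     wmh_volume_fraction = c(case = 0.45, control = 0.4),
                     wmh_fraction_cv_log = 0)
  expect_error(simulate_cohort(cfg), "grid too small")
})

test_that("config validation catches bad inputs", {
  expect_error(simulation_config(n_case = 0), "> 0")
  expect_error(simulation_config(wmh_volume_fraction = c(case = 0.7,
                                                         control = 0.1)),
               "\\(0, 0.5\\)")
  expect_error(simulation_config(penumbra_decay_mm = -1), ">= 0")
  expect_error(simulation_config(grid_shape = c(4, 4, 4)), ">= 8")
  expect_error(simulation_config(cognition_coefficients = c(myelin = 1)),
               "lacks")
})

test_that("a null configuration yields near-nominal one-sample rejection rates", {
  # all lesion effects zero: case and control maps differ only by noise, so
  # the penumbra difference-score tests should reject at roughly alpha.
  # Pooled over seeds and rings; the control-reference offset shared across
  # cases makes the test mildly anticonservative, hence the generous band.
  mp <- default_metric_params()
  mp$lesion_effect[] <- 0
  pvals <- c()
  for (seed in 1:8) {
    cfg <- simulation_config(grid_shape = c(26, 30, 26), n_case = 16,
                             n_control = 10, metric_params = mp,
                             metrics = c("chi_neg", "chi_pos", "fw"),
                             seed = 100 + seed)
    co <- simulate_cohort(cfg)
    res <- analyze_cohort(co, voxelwise = FALSE)
    pt <- res$penumbra_table
    pvals <- c(pvals, pt$p[pt$metric == "chi_neg"])
  }
  rate <- mean(pvals < 0.05)
  expect_lt(rate, 0.17)
  # and planted effects are detected in the same setting (sanity contrast)
  co2 <- simulate_cohort(simulation_config(grid_shape = c(26, 30, 26),
                                           n_case = 16, n_control = 10,
                                           metrics = c("chi_neg", "chi_pos",
                                                       "fw"),
                                           seed = 500))
  res2 <- analyze_cohort(co2, voxelwise = FALSE)
  pt2 <- res2$penumbra_table
  expect_lt(pt2$p[pt2$metric == "chi_neg" & pt2$roi == "wmh"], 1e-4)
})
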