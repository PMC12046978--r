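test_that("wm_mask_from_probability thresholds and erodes like the voxel oracle", {
  # all-zero probability -> empty mask
  empty <- wm_mask_from_probability(array(0, c(5, 5, 5)), erode_mm = 0)
  expect_false(any(empty))

  # solid cube, 1 mm grid, erode 1 mm -> shrunk by one voxel per face
  cube <- array(0, c(11, 11, 11))
  cube[3:9, 3:9, 3:9] <- 1
  er <- wm_mask_from_probability(cube, threshold = 0.5, erode_mm = 1,
                                 voxel_size_mm = c(1, 1, 1))
  want <- array(FALSE, c(11, 11, 11))
  want[4:8, 4:8, 4:8] <- TRUE
  expect_identical(er, want)

  # random probability field vs brute-force threshold + erosion
  set.seed(42)
  for (sp in list(c(1, 1, 1), c(1, 1.5, 2))) {
    prob <- array(runif(7 * 8 * 6), c(7, 8, 6))
    got <- suppressWarnings(
      wm_mask_from_probability(prob, threshold = 0.6, erode_mm = 1.6,
                               voxel_size_mm = sp))
    want <- brute_erode(array(prob > 0.6, dim(prob)), 1.6, sp)
    expect_identical(got, want)
  }

  # erosion radius below the voxel spacing: warn that it is a no-op
  expect_warning(
    wm_mask_from_probability(array(runif(4^3), c(4, 4, 4)), erode_mm = 1,
                             voxel_size_mm = c(2, 2, 2)),
    "no-op")
  expect_error(wm_mask_from_probability(array(2, c(3, 3, 3))), "\\[0, 1\\]")
})

test_that("derive_nawm is exact set algebra", {
  dm <- c(6, 7, 5)
  set.seed(7)
  wm <- random_mask(dm, 0.6)
  wmh <- random_mask(dm, 0.2) & wm
  lac <- random_mask(dm, 0.1)

  expect_identical(derive_nawm(wm, array(FALSE, dm), lac), wm & !lac)
  expect_false(any(derive_nawm(wm, wm, NULL)))
  expect_identical(derive_nawm(wm, wmh, lac), wm & !wmh & !lac)
  expect_error(derive_nawm(wm, array(FALSE, c(2, 2, 2))), "mismatch")
})

test_that("penumbra rings follow the distance definition", {
  dm <- c(9, 9, 9)
  wmh <- array(FALSE, dm)
  wmh[5, 5, 5] <- TRUE
  nawm <- !wmh
  rings <- penumbra_rings(wmh, nawm, step_mm = 2, max_mm = 10,
                          voxel_size_mm = c(1, 1, 1))
  expect_identical(rings[6, 5, 5], 1L)    # face neighbour, 1.0 mm
  expect_identical(rings[5, 5, 8], 2L)    # 3.0 mm
  expect_identical(rings[5, 5, 5], 0L)    # lesion voxel itself
  expect_error(penumbra_rings(array(FALSE, dm), nawm), "empty")
  expect_error(penumbra_rings(wmh, nawm, step_mm = 2, max_mm = 5),
               "multiple")
})

test_that("penumbra rings equal the iterative-dilation oracle", {
  set.seed(11)
  dm <- c(12, 13, 11)
  sp <- c(1, 1, 1)
  for (rep in 1:3) {
    wmh <- random_mask(dm, 0.05)
    if (!any(wmh)) wmh[6, 6, 6] <- TRUE
    nawm <- random_mask(dm, 0.7) & !wmh
    got <- penumbra_rings(wmh, nawm, 2, 10, sp)
    want <- dilation_rings(wmh, nawm, 2, 10, sp)
    expect_identical(got, want)
  }
})

test_that("ring voxel counts around a spherical lesion match analytic shells", {
  dm <- c(41, 41, 41)
  sp <- c(1, 1, 1)
  ctr <- c(21, 21, 21)
  co <- as.matrix(expand.grid(x = 1:41, y = 1:41, z = 1:41))
  dist_ctr <- sqrt(rowSums(sweep(co, 2, ctr)^2))
  r <- 6
  wmh <- array(dist_ctr <= r, dm)
  rings <- penumbra_rings(wmh, !wmh, 2, 10, sp)
  half_diag <- sqrt(3) / 2
  shell <- function(a, b) 4 * pi / 3 * (b^3 - a^3)
  for (k in 1:5) {
    cnt <- sum(rings == k)
    lo <- shell(r + 2 * (k - 1) + half_diag, r + 2 * k - half_diag)
    hi <- shell(max(0, r + 2 * (k - 1) - half_diag), r + 2 * k + half_diag)
    expect_gt(cnt, 0.95 * lo)
    expect_lt(cnt, 1.05 * hi)
  }
})

test_that("ring labels partition NAWM and nest monotonically", {
  co <- simulate_cohort(tiny_config(seed = 4))
  s <- co$subjects[[1]]
  ms <- s$masks
  expect_true(all(ms$rings[!ms$nawm] == 0))       # rings live inside NAWM
  expect_false(any(ms$nawm & ms$wmh))
  expect_false(any(ms$nawm & ms$lacunes))
  # cumulative region up to ring k nests
  d <- distance_to_mask(ms$wmh, ms$voxel_size_mm)
  prev <- ms$wmh
  for (k in 1:5) {
    cum <- ms$wmh | (ms$rings > 0 & ms$rings <= k)
    expect_true(all(cum[prev]))                   # superset of previous
    prev <- cum
  }
  # every labelled voxel's distance lies in its bin (lo, hi]
  for (k in 1:5) {
    dk <- d[ms$rings == k]
    expect_true(all(dk > 2 * (k - 1) & dk <= 2 * k))
  }
})

test_that("lesion frequency maps count subjects exactly", {
  dm <- c(6, 6, 6)
  m1 <- array(FALSE, dm); m1[1:2, , ] <- TRUE
  f1 <- lesion_frequency_map(list(m1), c(2, 2, 2))
  expect_true(all(f1$values[m1] == 100) && all(f1$values[!m1] == 0))

  m2 <- array(FALSE, dm); m2[5:6, , ] <- TRUE
  f2 <- lesion_frequency_map(list(m1, m2))
  expect_true(all(f2$values[m1 | m2] == 50))
  expect_true(all(f2$values[!(m1 | m2)] == 0))

  set.seed(3)
  masks <- replicate(7, random_mask(dm, 0.3), simplify = FALSE)
  f7 <- lesion_frequency_map(masks, c(1.5, 1.5, 1.5))
  tally <- Reduce(`+`, lapply(masks, function(m) array(as.numeric(m), dm)))
  expect_equal(f7$values, 100 * tally / 7)
  expect_true(all(f7$values >= 0 & f7$values <= 100))
  # sum over voxels x voxel volume / n = mean lesion volume
  voxvol <- prod(f7$voxel_size_mm)
  expect_equal(sum(f7$values / 100) * voxvol,
               mean(vapply(masks, function(m) sum(m) * voxvol, numeric(1))))
  expect_error(lesion_frequency_map(list()), "non-empty")
})

test_that("distance transform and ball morphology match brute force", {
  set.seed(21)
  for (sp in list(c(1, 1, 1), c(0.8, 1.3, 2))) {
    dm <- c(8, 7, 9)
    m <- random_mask(dm, 0.12)
    expect_equal(distance_to_mask(m, sp), brute_edt(m, sp), tolerance = 1e-12)
    expect_identical(ball_dilate(m, 2.2, sp), brute_dilate(m, 2.2, sp))
    big <- random_mask(dm, 0.7)
    expect_identical(ball_erode(big, 1.4, sp), brute_erode(big, 1.4, sp))
  }
})
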