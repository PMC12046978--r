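test_that("two-sided t p-values reproduce printed worked examples", {
  expect_equal(two_sided_p_from_t(0, 7), 1)
  expect_equal(round(two_sided_p_from_t(-2.63, 59), 3), 0.011)
  expect_equal(round(two_sided_p_from_t(-2.76, 36.46), 3), 0.009)
  expect_equal(round(two_sided_p_from_t(-1.93, 78), 3), 0.057)
  expect_error(two_sided_p_from_t(1, 0), "positive")
})

test_that("one-sample test matches the closed form and t.test", {
  r <- one_sample_test(c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3))
  expect_equal(r$df, 2)
  expect_equal(r$d, 2)

  r0 <- one_sample_test(c(4, 5, 6, 7), mu = 5.5)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$d, 0)

  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(5 + i, mean = runif(1, -1, 1))
    mu <- runif(1, -0.5, 0.5)
    got <- one_sample_test(x, mu)
    want <- t.test(x, mu = mu)
    expect_equal(got$t, unname(want$statistic))
    expect_equal(got$p, want$p.value)
    expect_equal(got$d, got$t / sqrt(length(x)))   # definitional identity
  }
  expect_error(one_sample_test(rep(1, 5)), "variance")
})

test_that("one-sample Cohen's d and its CI reproduce the printed table rows", {
  expect_equal(round(cohens_d_one_sample(-20.54, 60), 2), -2.65)
  expect_equal(round(cohens_d_one_sample(-9.06, 60), 2), -1.17)
  expect_equal(cohens_d_one_sample(0, 12), 0)

  ci0 <- d_confidence_interval(0, 60)
  expect_equal(ci0[2], qnorm(0.975) / sqrt(60))
  expect_equal(ci0[1], -ci0[2])

  d <- cohens_d_one_sample(-9.06, 60)
  expect_equal(round(d_confidence_interval(d, 60), 2), c(-1.50, -0.84))

  w <- function(d) diff(d_confidence_interval(d, 40))
  expect_true(w(0) < w(0.8) && w(0.8) < w(2.5))
})

test_that("two-sample test agrees with t.test in both variance modes", {
  a <- c(2, 2); b <- c(3.001, 2.999)
  expect_lt(welch_two_sample_test(a, b)$p, 0.01)
  same <- c(1, 2, 3, 4)
  r <- welch_two_sample_test(same, same)
  expect_equal(r$t, 0); expect_equal(r$p, 1)

  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(6 + i); y <- rnorm(9, 0.5, 2)
    for (ve in c(TRUE, FALSE)) {
      got <- welch_two_sample_test(x, y, var_equal = ve)
      want <- t.test(y, x, var.equal = ve)
      expect_equal(got$t, unname(want$statistic))
      expect_equal(got$df, unname(want$parameter))
      expect_equal(got$p, want$p.value)
    }
  }
  expect_error(welch_two_sample_test(c(1, 1), c(2, 2)), "variance")
})

test_that("pearson test matches cor.test and the printed example", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)

  # r = -0.49 at df = 18 gives the printed p = 0.03
  t_paper <- -0.49 * sqrt(18 / (1 - 0.49^2))
  expect_equal(round(two_sided_p_from_t(t_paper, 18), 2), 0.03)

  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(10 + i); y <- 0.4 * x + rnorm(10 + i)
    got <- pearson_test(x, y)
    want <- cor.test(x, y)
    expect_equal(got$r, unname(want$estimate))
    expect_equal(got$p, want$p.value)
    expect_equal(got$df, unname(want$parameter))
  }
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "constant")
})

test_that("partial R2 reproduces printed ridge effect sizes", {
  expect_equal(round(partial_r2(2.65, 54.6), 2), 0.11)
  expect_equal(round(partial_r2(2.91, 53.4), 2), 0.14)
  expect_equal(partial_r2(0, 10), 0)
  expect_true(all(partial_r2(rnorm(20, sd = 5), 7) < 1))
})

test_that("BH step-up rejects exactly the step-up set", {
  expect_identical(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_identical(bh_fdr(0.01), TRUE)

  # step-up hand computation: thresholds k * 0.05 / 7; only the two smallest
  # pass (0.039 > 3 * 0.05 / 7 = 0.0214)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.9)
  expect_identical(bh_fdr(p, 0.05), c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                      FALSE, FALSE))

  set.seed(4)
  for (i in 1:10) {
    p <- runif(50)^2
    expect_identical(bh_fdr(p, 0.05), unname(p.adjust(p, "BH") <= 0.05))
  }
  expect_identical(bh_fdr(numeric(0)), logical(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("voxelwise group GLM finds planted signal and honours the extent rule", {
  dm <- c(12, 12, 12)
  sp <- c(2, 2, 2)
  mask <- array(TRUE, dm)
  n1 <- 8; n2 <- 8
  grp <- c(rep(0, n1), rep(1, n2))

  # planted 5x5x5 block shift with SNR >> 1
  set.seed(9)
  block <- array(FALSE, dm); block[4:8, 4:8, 4:8] <- TRUE
  maps <- lapply(seq_along(grp), function(i) {
    a <- array(rnorm(prod(dm)), dm)
    if (grp[i] == 1) a[block] <- a[block] + 6
    a
  })
  res <- voxelwise_group_glm(maps, grp, mask, alpha = 0.05, extent_k = 10,
                             voxel_size_mm = sp)
  expect_gte(sum(res$significant & block), 0.9 * sum(block))
  halo <- ball_dilate(block, 2 * max(sp), sp)   # one-voxel halo
  expect_false(any(res$significant & !halo))
  expect_gte(nrow(res$clusters), 1)
  expect_true(res$clusters$peak_t[1] > 0)

  # a significant component smaller than extent_k is dropped
  small <- array(FALSE, dm); small[2:4, 2:4, 2] <- TRUE   # 9 voxels
  maps2 <- lapply(seq_along(grp), function(i) {
    a <- array(rnorm(prod(dm), sd = 0.05), dm)
    if (grp[i] == 1) a[small] <- a[small] + 10
    a
  })
  res2 <- voxelwise_group_glm(maps2, grp, mask, alpha = 0.05, extent_k = 10,
                              voxel_size_mm = sp)
  expect_identical(nrow(res2$clusters), 0L)
  expect_false(any(res2$significant))

  # identically generated groups with zero residual variance: voxels are
  # excluded rather than tested
  flat <- lapply(seq_along(grp), function(i) array(grp[i], dm))
  res3 <- voxelwise_group_glm(flat, grp, mask, voxel_size_mm = sp)
  expect_identical(sum(res3$significant), 0L)
  expect_equal(res3$n_excluded, prod(dm))
})
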