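ridge_oracle <- function(X, y, lambda) {
  # dense matrix-algebra route: explicit H, explicit traces
  Xs <- scale(X)
  yc <- y - mean(y)
  n <- nrow(Xs); p <- ncol(Xs)
  A <- crossprod(Xs) + diag(lambda, p)
  H <- Xs %*% solve(A) %*% t(Xs)
  beta <- drop(solve(A, crossprod(Xs, yc)))
  res <- yc - drop(H %*% yc)
  edf <- n - sum(diag(2 * H - H %*% t(H)))
  sigma2 <- sum(res^2) / edf
  covb <- sigma2 * solve(A) %*% crossprod(Xs) %*% solve(A)
  tv <- beta / sqrt(diag(covb))
  list(beta = beta, edf = edf, t = tv,
       p = 2 * pt(abs(tv), edf, lower.tail = FALSE),
       r2 = 1 - sum(res^2) / sum(yc^2))
}

test_that("ridge at lambda = 0 is OLS, and large lambda shrinks to zero", {
  set.seed(10)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- drop(X %*% c(1, -2, 0.5, 0)) + rnorm(20)

  fit0 <- ridge_fit(X, y, lambda = 0)
  Xs <- scale(X); yc <- y - mean(y)
  ols <- lm(yc ~ Xs - 1)
  expect_equal(unname(fit0$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(fit0$edf, 20 - 4, tolerance = 1e-10)
  sm <- summary(ols)
  expect_equal(unname(fit0$t), unname(sm$coefficients[, "t value"]),
               tolerance = 1e-8)
  expect_equal(unname(fit0$p), unname(sm$coefficients[, "Pr(>|t|)"]),
               tolerance = 1e-8)

  fit_big <- ridge_fit(X, y, lambda = 1e9)
  expect_true(all(abs(fit_big$coefficients) < 1e-6))
  expect_equal(fit_big$edf, 20, tolerance = 1e-5)
})

test_that("ridge inference equals the dense matrix-algebra oracle", {
  set.seed(11)
  X <- matrix(rnorm(6 * 2), 6, 2)
  y <- rnorm(6)
  got <- ridge_fit(X, y, lambda = 1)
  want <- ridge_oracle(X, y, 1)
  expect_equal(unname(got$coefficients), want$beta, tolerance = 1e-10)
  expect_equal(got$edf, want$edf, tolerance = 1e-10)
  expect_equal(unname(got$t), want$t, tolerance = 1e-10)
  expect_equal(unname(got$p), want$p, tolerance = 1e-10)
  expect_equal(got$r2, want$r2, tolerance = 1e-10)
  expect_equal(unname(got$partial_r2),
               want$t^2 / (want$t^2 + want$edf), tolerance = 1e-10)

  # larger random fixtures at several penalties
  for (lam in c(0.3, 2, 17)) {
    Xr <- matrix(rnorm(15 * 5), 15, 5)
    yr <- rnorm(15)
    g <- ridge_fit(Xr, yr, lam)
    w <- ridge_oracle(Xr, yr, lam)
    expect_equal(unname(g$coefficients), w$beta, tolerance = 1e-8)
    expect_equal(g$edf, w$edf, tolerance = 1e-8)
  }
})

test_that("effective df follows the singular-value identity and is monotone", {
  set.seed(12)
  X <- matrix(rnorm(8 * 3), 8, 3)
  Xs <- scale(X)
  d2 <- svd(Xs)$d^2
  lam <- 0.7
  want <- 8 - sum(d2 * (d2 + 2 * lam) / (d2 + lam)^2)
  expect_equal(effective_df(X, lam), want, tolerance = 1e-10)
  expect_equal(effective_df(X, 0), 8 - 3, tolerance = 1e-10)
  expect_equal(effective_df(X, 1e12), 8, tolerance = 1e-6)
  lams <- c(0.01, 0.1, 1, 10, 100)
  edfs <- vapply(lams, function(l) effective_df(X, l), numeric(1))
  expect_true(all(diff(edfs) > 0))
  expect_true(all(edfs <= 8))
  expect_error(effective_df(X, -1), ">= 0")
})

test_that("GCV lambda selection is deterministic and attains the grid minimum", {
  set.seed(13)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y_exact <- drop(scale(X) %*% c(1, 2, -1))
  lam_exact <- auto_lambda(X, y_exact)
  expect_lt(as.numeric(lam_exact), 1e-5)     # no shrinkage needed

  yn <- rnorm(12)
  Xn <- matrix(rnorm(12 * 9), 12, 9)
  lam_noise <- auto_lambda(Xn, yn)
  expect_gt(as.numeric(lam_noise), 0)
  gcv <- attr(lam_noise, "gcv")
  # the returned lambda is at least as good as every grid point
  des_gcv <- function(lam) {
    f <- ridge_fit(Xn, yn, lam)
    sum(f$residuals^2) / (12 - f$tr_h)^2
  }
  expect_lte(des_gcv(as.numeric(lam_noise)), min(gcv) + 1e-12)
  expect_identical(as.numeric(lam_noise),
                   as.numeric(auto_lambda(Xn, yn)))   # deterministic

  expect_error(auto_lambda(X, rep(1, 30)), "zero variance")
})

test_that("ridge refuses invalid inputs", {
  set.seed(14)
  X <- matrix(rnorm(10 * 2), 10, 2)
  y <- rnorm(10)
  expect_error(ridge_fit(X, y, lambda = -0.1), ">= 0")
  expect_error(ridge_fit(X, y, lambda = 1, standardize = FALSE),
               "standardized")
  expect_silent(ridge_fit(scale(X), y, lambda = 1, standardize = FALSE))
  Xc <- cbind(X, 0)
  expect_error(ridge_fit(Xc, y, 1), "constant")
})
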