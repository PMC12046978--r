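# Processing-speed compound from timed Trail Making Tests.
#
# Raw TMT-A/B completion times (seconds; higher = slower) are stratified
# against an age x education normative table, averaged, power transformed
# (Box-Cox, MLE lambda) to tame their right skew, then negated and
# z-standardized against the control group so that higher = faster and the
# control mean is 0 / SD 1.

#' Construct a normative table for timed-test stratification
#'
#' @param df data.frame with columns `age_lo`, `age_hi`, `edu_lo`, `edu_hi`,
#'   `tmt_a_mean`, `tmt_a_sd`, `tmt_b_mean`, `tmt_b_sd`. Strata must have
#'   positive SDs; `[lo, hi)` intervals are expected to partition the
#'   covariate space.
#' @return object of class `norm_table`.
#' @export
norm_table <- function(df) {
  need <- c("age_lo", "age_hi", "edu_lo", "edu_hi",
            "tmt_a_mean", "tmt_a_sd", "tmt_b_mean", "tmt_b_sd")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("norm table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("empty norm table")
  if (any(df$tmt_a_sd <= 0) || any(df$tmt_b_sd <= 0))
    stop("stratum SDs must be positive")
  structure(as.data.frame(df), class = c("norm_table", "data.frame"))
}

#' Simulate a normative table
#'
#' Stand-in for a published normative source: per age x education stratum,
#' mean and SD of TMT-A and TMT-B completion seconds, with completion times
#' increasing with age and decreasing with education plus small seeded
#' stratum-level jitter.
#'
#' @param age_bins increasing numeric breaks for age strata
#'   (`[b_i, b_{i+1})`).
#' @param education_bins increasing numeric breaks for education strata.
#' @param seed integer seed; the table is deterministic given the seed.
#' @return a [norm_table()].
#' @export
simulate_norm_table <- function(age_bins = c(18, 45, 60, 75, 95),
                                education_bins = c(0, 12, 16, 30),
                                seed = 1) {
  if (length(age_bins) < 2L || length(education_bins) < 2L)
    stop("need at least one stratum per axis (two breaks)")
  if (is.unsorted(age_bins, strictly = TRUE) ||
      is.unsorted(education_bins, strictly = TRUE))
    stop("bins must be strictly increasing")
  na <- length(age_bins) - 1L
  ne <- length(education_bins) - 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- expand.grid(a = seq_len(na), e = seq_len(ne))
  jit <- matrix(runif(nrow(rows) * 4, -2, 2), ncol = 4)
  df <- data.frame(
    age_lo = age_bins[rows$a], age_hi = age_bins[rows$a + 1L],
    edu_lo = education_bins[rows$e], edu_hi = education_bins[rows$e + 1L],
    tmt_a_mean = 26 + 7 * (rows$a - 1) - 3 * (rows$e - 1) + jit[, 1],
    tmt_a_sd = 9 + 2 * (rows$a - 1) + 0.2 * abs(jit[, 2]),
    tmt_b_mean = 62 + 18 * (rows$a - 1) - 7 * (rows$e - 1) + 3 * jit[, 3],
    tmt_b_sd = 24 + 5 * (rows$a - 1) + 0.5 * abs(jit[, 4]))
  norm_table(df)
}

find_stratum <- function(norms, age, education) {
  hit <- which(age >= norms$age_lo & age < norms$age_hi &
               education >= norms$edu_lo & education < norms$edu_hi)
  if (length(hit) != 1L) {
    ctr_a <- (norms$age_lo + norms$age_hi) / 2
    ctr_e <- (norms$edu_lo + norms$edu_hi) / 2
    nearest <- which.min((ctr_a - age)^2 + (ctr_e - education)^2)
    stop(sprintf(
      "covariates (age %.5g, education %.5g) fall in %s stratum; nearest stratum is age [%g, %g), education [%g, %g)",
      age, education, if (length(hit)) "more than one" else "no",
      norms$age_lo[nearest], norms$age_hi[nearest],
      norms$edu_lo[nearest], norms$edu_hi[nearest]))
  }
  hit
}

#' Stratify a timed-test score against normative data
#'
#' `(raw - stratum mean) / stratum SD` for the age x education stratum the
#' subject falls into. Higher stratified scores still mean slower
#' performance.
#'
#' @param raw_seconds completion time(s) in seconds, `> 0` (vectorised).
#' @param age,education subject covariates (vectorised).
#' @param norms a [norm_table()].
#' @param test `"tmt_a"` or `"tmt_b"`.
#' @return stratified score(s).
#' @export
stratify_tmt <- function(raw_seconds, age, education, norms,
                         test = c("tmt_a", "tmt_b")) {
  test <- match.arg(test)
  if (any(raw_seconds <= 0)) stop("'raw_seconds' must be positive")
  k <- length(raw_seconds)
  age <- rep_len(age, k); education <- rep_len(education, k)
  mcol <- paste0(test, "_mean"); scol <- paste0(test, "_sd")
  vapply(seq_len(k), function(i) {
    s <- find_stratum(norms, age[i], education[i])
    (raw_seconds[i] - norms[[mcol]][s]) / norms[[scol]][s]
  }, numeric(1))
}

#' Box-Cox maximum-likelihood exponent
#'
#' Profiles the Box-Cox log-likelihood
#' `-n/2 log(sigma_hat^2(z)) + (lambda - 1) sum(log y)` over a grid with
#' local refinement.
#'
#' @param y positive observations.
#' @param grid candidate exponents.
#' @return the MLE `lambda`, with the grid log-likelihoods in attribute
#'   `"loglik"`.
#' @export
boxcox_lambda <- function(y, grid = seq(-3, 3, by = 0.05)) {
  if (any(y <= 0)) stop("Box-Cox requires positive data")
  if (sd(y) == 0) stop("degenerate (constant) data")
  n <- length(y)
  slog <- sum(log(y))
  ll <- function(lam) {
    z <- if (abs(lam) < 1e-12) log(y) else (y^lam - 1) / lam
    v <- mean((z - mean(z))^2)
    -n / 2 * log(v) + (lam - 1) * slog
  }
  lls <- vapply(grid, ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  lam <- if (lo < hi) optimize(ll, c(lo, hi), maximum = TRUE)$maximum
         else grid[i]
  if (ll(lam) < lls[i]) lam <- grid[i]
  structure(lam, loglik = lls, grid = grid)
}

boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Processing-speed compound score
#'
#' Averages the stratified TMT-A and TMT-B scores, shifts the pooled compound
#' to positivity, applies a Box-Cox power transform (MLE exponent unless
#' `lambda` is fixed), negates so that higher = faster, and z-standardizes
#' against the control group (control mean 0, SD 1). The composition is
#' strictly decreasing in completion time for every exponent, so the
#' orientation guarantee does not depend on the estimated `lambda`.
#'
#' @param strat_a,strat_b stratified TMT-A/B scores (finite, equal length).
#' @param group factor or character: `"control"` entries define the
#'   standardization reference; everything else is treated as a case. With
#'   `NULL`, the pooled sample is the reference.
#' @param lambda optional fixed Box-Cox exponent; default is the MLE.
#' @return object of class `cognition_score`: list with `compound`
#'   (final score vector), `compound_raw`, `lambda`, `shift`,
#'   `ref_mean`, `ref_sd`.
#' @export
processing_speed_compound <- function(strat_a, strat_b, group = NULL,
                                      lambda = NULL) {
  if (length(strat_a) != length(strat_b))
    stop("stratified score vectors must have equal length")
  if (any(!is.finite(strat_a)) || any(!is.finite(strat_b)))
    stop("stratified scores must be finite")
  raw <- (strat_a + strat_b) / 2
  if (sd(raw) == 0) stop("degenerate pooled compound (zero variance)")
  shift <- 1 - min(raw)                 # positivity shift for the power family
  ypos <- raw + shift
  if (is.null(lambda)) lambda <- as.numeric(boxcox_lambda(ypos))
  z <- -boxcox_transform(ypos, lambda)  # negate: higher = faster
  is_ctrl <- if (is.null(group)) rep(TRUE, length(z))
             else as.character(group) == "control"
  if (!any(is_ctrl)) is_ctrl <- rep(TRUE, length(z))
  ref_mean <- mean(z[is_ctrl]); ref_sd <- sd(z[is_ctrl])
  if (is.na(ref_sd) || ref_sd == 0) { ref_sd <- sd(z); ref_mean <- mean(z) }
  structure(list(compound = (z - ref_mean) / ref_sd, compound_raw = raw,
                 lambda = lambda, shift = shift, ref_mean = ref_mean,
                 ref_sd = ref_sd),
            class = "cognition_score")
}
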