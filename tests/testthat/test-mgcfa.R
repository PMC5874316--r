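test_that("implied moments follow the factor-model closed form", {
  m <- implied_moments(c(1, 1, 1), c(1, 1, 1))
  expect_equal(m$cov, tcrossprod(rep(1, 3)) + diag(3))
  expect_equal(m$mean, rep(0, 3))

  m0 <- implied_moments(rep(0, 4), rep(2, 4))
  expect_equal(m0$cov, diag(2, 4))

  m2 <- implied_moments(c(1, 0.5), c(1, 1))
  expect_equal(m2$cov[1, 2], 0.5)
  expect_equal(m2$cov[2, 2], 1.25)
})

test_that("the ML discrepancy is zero iff the matrices agree, else positive", {
  S <- diag(2, 2)
  expect_equal(fml_discrepancy(S, S), 0)

  # hand evaluation: ln|I| - ln|2I| + tr(2I * I) - 2 = -ln 4 + 4 - 2
  expect_equal(fml_discrepancy(2 * diag(2), diag(2)), 2 - log(4),
               tolerance = 1e-12)
  # the discrepancy is not symmetric in its arguments
  expect_equal(fml_discrepancy(diag(2), 2 * diag(2)), log(4) - 1,
               tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    A <- crossprod(matrix(rnorm(36), 6, 6)) / 6 + diag(6)
    B <- crossprod(matrix(rnorm(36), 6, 6)) / 6 + diag(6)
    expect_gt(fml_discrepancy(A, B), 0)
    expect_equal(fml_discrepancy(A, A), 0, tolerance = 1e-10)
  }
})

test_that("three-indicator fit recovers the tetrad closed form at F = 0", {
  set.seed(8)
  samp <- make_sample(p = 3, n = 2000, seed = 8)
  # duplicate one group into both slots: the constrained fit then equals a
  # single-group fit of a just-identified model
  samp$group2 <- samp$group1
  fit <- fit_mgcfa(samp, loadings_equal = TRUE)
  expect_true(fit$converged)
  expect_lt(fit$statistic, 1e-6)
  S <- stats::cov(samp$group1)
  lam1_tetrad <- sqrt(S[1, 2] * S[1, 3] / S[2, 3])
  expect_equal(fit$loadings[[1]][1], lam1_tetrad, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("ML estimates are consistent for the generating model", {
  samp <- make_sample(p = 5, n = 1e5, seed = 12)
  fit <- fit_mgcfa(samp, loadings_equal = TRUE)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$loadings[[1]] - 1)), 0.02)
  expect_lt(max(abs(fit$uniquenesses - 1)), 0.02)
  expect_lt(max(abs(fit$intercepts)), 0.02)
})

test_that("constrained fit never beats the unconstrained fit", {
  for (seed in 1:8) {
    samp <- make_sample(p = 4, n = 80, seed = seed, pct = 0.25)
    fc <- fit_mgcfa(samp, loadings_equal = TRUE)
    fu <- fit_mgcfa(samp, loadings_equal = FALSE)
    if (fc$converged && fu$converged) {
      expect_gte(fc$statistic - fu$statistic, -1e-6)
      expect_equal(fc$df - fu$df, 4L)
    }
  }
})

test_that("chi-square difference test matches the reference distribution", {
  # survival-function oracles: qchisq checks computed independently
  fit_c <- structure(list(statistic = 100 + 18.307, df = 100L,
                          loadings_equal = TRUE, converged = TRUE, p = 10L),
                     class = "ml_fit")
  fit_u <- structure(list(statistic = 100, df = 90L,
                          loadings_equal = FALSE, converged = TRUE, p = 10L),
                     class = "ml_fit")
  tst <- chisq_difference(fit_c, fit_u)
  expect_equal(tst$df, 10L)
  expect_equal(tst$p_value, 0.050, tolerance = 0.01)
  expect_false(tst$reject)

  fit_c$statistic <- 100 + 3.84
  fit_c$df <- 91L
  tst1 <- chisq_difference(fit_c, fit_u)
  expect_equal(tst1$df, 1L)
  expect_equal(tst1$p_value, 0.050, tolerance = 0.01)

  # identical fits: delta 0, p = 1, no rejection
  fit_c$statistic <- 100
  fit_c$df <- 100L
  tst0 <- chisq_difference(fit_c, fit_u)
  expect_equal(tst0$statistic, 0)
  expect_equal(tst0$p_value, 1)
  expect_false(tst0$reject)

  fit_u$converged <- FALSE
  expect_error(chisq_difference(fit_c, fit_u), "converged")
})

test_that("power of the ML test rises with sample size and non-invariance", {
  rate <- function(n, pct, reps = 60) {
    cond <- null_condition(p = 4, n = n, pct = pct)
    run_cell(cond, "ml", reps = reps, seed = 21)$rejection_rate
  }
  expect_gt(rate(400, 0.5), rate(50, 0.5) - 0.05)
  expect_gt(rate(400, 0.5), 0.9)
  expect_lt(rate(400, 0), 0.2)
})

test_that("ML robustness to latent skewness depends on what 'skewness 2' means", {
  # slant-parameter skew-normal latents (moment skewness ~0.45) leave the
  # chi-square difference test calibrated at n = 200; a latent trait whose
  # third standardized moment truly equals 2 (standardized gamma, excess
  # kurtosis 6) inflates it well beyond the Bradley band
  rate_for <- function(gen) {
    cond <- study_condition(latent_spec("skewed", 2, generator = gen),
                            p = 10, pct_non_invariant = 0, n_per_group = 200)
    run_cell(cond, "ml", reps = 300, seed = 71)$rejection_rate
  }
  expect_lte(rate_for("azzalini_slant"), 0.09)
  expect_gte(rate_for("moment_matched_gamma"), 0.09)
})

test_that("applied-mode ML test runs from a delimited file and writes a report", {
  samp <- make_sample(p = 4, n = 150, seed = 3, pct = 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  rep_file <- withr::local_tempfile(fileext = ".csv")
  write_sample(samp, f)
  res <- test_invariance(f, method = "ml", report = rep_file)
  expect_s3_class(res$test, "invariance_test")
  tab <- read.csv(rep_file)
  expect_equal(tab$statistic, res$test$statistic)
  expect_equal(tab$df, 4L)
})
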