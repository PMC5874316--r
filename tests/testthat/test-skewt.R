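test_that("skew-t log-density reduces to the multivariate normal", {
  set.seed(14)
  p <- 4
  lam <- c(1, 0.8, 1.2, 1)
  scale <- tcrossprod(lam) + diag(p)
  mu <- c(0.5, 0, -0.5, 1)
  x <- matrix(rnorm(200 * p), 200, p) %*% chol(scale)
  x <- sweep(x, 2, mu, "+")
  ld_mst <- dmst(x, mu, scale, delta = rep(0, p), nu = 1e6)
  # hand-coded multivariate normal log-density as the oracle
  cS <- chol(scale)
  z <- backsolve(cS, t(sweep(x, 2, mu)), transpose = TRUE)
  ld_mvn <- -0.5 * colSums(z^2) - sum(log(diag(cS))) - (p / 2) * log(2 * pi)
  expect_lt(max(abs(ld_mst - ld_mvn)), 1e-4)
})

test_that("univariate skew-t density integrates to one", {
  f <- function(x) {
    dmst(matrix(x, ncol = 1), mu = 0.3, scale = matrix(1.5, 1, 1),
         delta = 0.8, nu = 5, log = FALSE)
  }
  val <- stats::integrate(f, -Inf, Inf)$value
  expect_lt(abs(val - 1), 0.01)
})

test_that("skew-t simulation matches its closed-form mean and symmetry limits", {
  p <- 3
  lam <- rep(1, p)
  scale <- tcrossprod(lam) + diag(p)
  mu <- c(1, 0, -1)
  set.seed(15)
  x0 <- rmst(1e6, mu, scale, delta = rep(0, p), nu = 50)
  expect_lt(max(abs(vapply(seq_len(p), function(j) skewness_of(x0[, j]),
                           numeric(1)))), 0.02)

  delta <- c(1, 0.5, 0)
  set.seed(16)
  x1 <- rmst(1e6, mu, scale, delta = delta, nu = 8)
  oracle_mean <- invarsim:::mst_mean(mu, delta, nu = 8)
  expect_lt(max(abs(colMeans(x1) - oracle_mean)), 0.01)

  set.seed(17)
  a <- rmst(100, mu, scale, delta, 8)
  set.seed(17)
  b <- rmst(100, mu, scale, delta, 8)
  expect_identical(a, b)
})

test_that("skew-t ML recovers generating parameters", {
  p <- 5
  lam <- rep(1, p)
  scale <- tcrossprod(lam) + diag(p)
  delta <- rep(0.8, p)
  set.seed(18)
  samp <- structure(list(group1 = rmst(2000, rep(0, p), scale, delta, 8),
                         group2 = rmst(2000, rep(0, p), scale, delta, 8)),
                    class = "two_group_sample")
  colnames(samp$group1) <- colnames(samp$group2) <- paste0("V", 1:p)
  fit <- fit_skewt_mgcfa(samp, loadings_equal = TRUE)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$loadings[[1]] - lam)), 0.1)
  expect_gt(mean(fit$delta), 0.3)
})

test_that("with skewness fixed at zero the skew-t fit matches normal-theory ML", {
  samp <- make_sample(p = 4, n = 1500, seed = 19)
  samp$group2 <- samp$group1
  fit_st <- fit_skewt_mgcfa(samp, loadings_equal = TRUE,
                            fix_delta = rep(0, 4), fix_nu = 1e6)
  # oracle: normal-theory ML on the likelihood-scale (divisor n) covariance
  n <- nrow(samp$group1)
  S_n <- stats::cov(samp$group1) * (n - 1) / n
  ml <- invarsim:::ml_fit_groups(list(S_n, S_n), list(n, n),
                                 equal_loadings = TRUE)
  expect_lt(max(abs(fit_st$loadings[[1]] - ml$loadings[[1]])), 1e-3)
  expect_lt(max(abs(fit_st$uniquenesses - ml$uniquenesses)), 2e-3)
})

test_that("skew-t parameter count exceeds the normal model by p + 1", {
  samp <- make_sample(p = 4, n = 300, seed = 20, skew = 2)
  fit <- fit_skewt_mgcfa(samp, loadings_equal = TRUE, maxit = 5)
  # normal constrained model: intercepts + loadings + uniquenesses = 3p
  expect_equal(fit$npar, 3L * 4L + 4L + 1L)
})

test_that("the likelihood-ratio invariance test behaves like the ML version", {
  fit_c <- structure(list(loglik = -500, loadings_equal = TRUE,
                          converged = TRUE, p = 10L), class = "skewt_fit")
  fit_u <- structure(list(loglik = -500 + 18.307 / 2, loadings_equal = FALSE,
                          converged = TRUE, p = 10L), class = "skewt_fit")
  tst <- skewt_invariance_test(fit_c, fit_u)
  expect_equal(tst$df, 10L)
  expect_equal(tst$p_value, 0.050, tolerance = 0.01)

  fit_u$loglik <- -500
  tst0 <- skewt_invariance_test(fit_c, fit_u)
  expect_equal(tst0$statistic, 0)
  expect_equal(tst0$p_value, 1)

  fit_u$loglik <- -501  # worse than the nested model: optimization failure
  expect_error(skewt_invariance_test(fit_c, fit_u), "negative")
})

test_that("skew-t estimation fails on a nonzero share of small samples", {
  # estimation failures (degenerate boundary modes) are themselves a study
  # outcome and are recorded by the convergence bookkeeping
  cond <- null_condition(p = 6, n = 25, skew = 2, pct = 0)
  cell <- run_cell(cond, "skewt", reps = 10, seed = 30)
  expect_lt(cell$convergence_rate, 1)
  expect_true(is.na(cell$rejection_rate) || cell$rejection_rate >= 0)
})
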