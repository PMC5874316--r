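test_that("chain specs track their retained draw count", {
  expect_equal(chain_spec()$retained, 5000L)
  expect_equal(reduced_chain()$retained, 1000L)
  expect_error(chain_spec(post = 10, thin = 20))
})

test_that("conjugate regression update matches an independent ridge oracle", {
  set.seed(51)
  D <- cbind(1, rnorm(40), rnorm(40))
  y <- D %*% c(0.5, 1, -1) + rnorm(40, sd = 0.7)
  sigma2 <- 0.49
  v0 <- 10
  post <- invarsim:::conj_reg_posterior(D, y, sigma2, v0)
  # oracle: augmented least squares - prior as pseudo-observations
  Daug <- rbind(D / sqrt(sigma2), diag(3) / sqrt(v0))
  yaug <- c(y / sqrt(sigma2), rep(0, 3))
  beta_aug <- qr.coef(qr(Daug), yaug)
  expect_equal(post$mean, unname(beta_aug), tolerance = 1e-10)
  expect_equal(post$cov, solve(crossprod(Daug)), tolerance = 1e-10)
})

test_that("compiled and reference samplers agree on the posterior", {
  samp <- make_sample(p = 3, n = 150, seed = 52)
  ch <- chain_spec(post = 3000, burn = 500, thin = 1)
  set.seed(1)
  d_cpp <- gibbs_mgcfa(samp, chain = ch, engine = "cpp")
  set.seed(2)
  d_r <- gibbs_mgcfa(samp, chain = ch, engine = "r")
  expect_equal(d_cpp$retained, 3000L)
  expect_equal(d_r$retained, 3000L)
  expect_lt(max(abs(colMeans(d_cpp$loadings1) - colMeans(d_r$loadings1))), 0.1)
  expect_lt(max(abs(colMeans(d_cpp$uniquenesses) -
                      colMeans(d_r$uniquenesses))), 0.1)
})

test_that("posterior means agree with ML at large n (Bernstein-von Mises)", {
  samp <- make_sample(p = 4, n = 5000, seed = 53)
  set.seed(3)
  draws <- gibbs_mgcfa(samp, chain = chain_spec(post = 3000, burn = 500,
                                                thin = 1))
  ml <- fit_mgcfa(samp, loadings_equal = FALSE)
  expect_lt(max(abs(colMeans(draws$loadings1) - ml$loadings[[1]])), 0.05)
  expect_lt(max(abs(colMeans(draws$loadings2) - ml$loadings[[2]])), 0.05)
})

test_that("posterior spread shrinks by more than 10x from n = 2 to n = 10000", {
  ch <- chain_spec(post = 2000, burn = 500, thin = 1)
  set.seed(4)
  tiny <- make_sample(p = 3, n = 2, seed = 54)
  big <- make_sample(p = 3, n = 5000, seed = 54)
  sd_tiny <- apply(gibbs_mgcfa(tiny, chain = ch)$loadings1, 2, sd)
  sd_big <- apply(gibbs_mgcfa(big, chain = ch)$loadings1, 2, sd)
  expect_true(all(sd_tiny > 10 * sd_big))
})

test_that("credibility intervals follow the draw quantiles", {
  # point mass away from zero: degenerate interval, rejection
  d1 <- fake_draws(matrix(0.3, 500, 2))
  dec1 <- summarize_differences(d1)
  expect_true(all(dec1$intervals$lower == 0.3 & dec1$intervals$upper == 0.3))
  expect_true(dec1$reject)

  # standard normal draws: interval near (-1.96, 1.96), containing zero
  set.seed(55)
  d2 <- fake_draws(matrix(rnorm(5000), 5000, 1))
  dec2 <- summarize_differences(d2)
  expect_lt(abs(dec2$intervals$lower + 1.96), 0.08)
  expect_lt(abs(dec2$intervals$upper - 1.96), 0.08)
  expect_false(dec2$reject)

  # symmetric draws about zero never reject
  d3 <- fake_draws(cbind(c(rnorm(2500), -rnorm(2500))))
  expect_false(summarize_differences(d3)$reject)

  # bonferroni widening makes per-indicator intervals strictly wider
  set.seed(56)
  d4 <- fake_draws(matrix(rnorm(4000), 2000, 2))
  raw <- summarize_differences(d4, multiplicity = "none")
  adj <- summarize_differences(d4, multiplicity = "bonferroni")
  expect_true(all(adj$intervals$lower < raw$intervals$lower))
  expect_true(all(adj$intervals$upper > raw$intervals$upper))
  expect_equal(adj$per_indicator_level, 1 - 0.05 / 2)

  expect_error(summarize_differences(fake_draws(matrix(0, 50, 1))),
               "at least 100")
})

test_that("split-Rhat and ESS diagnose healthy and pathological chains", {
  set.seed(57)
  good <- fake_draws(matrix(rnorm(4000), 2000, 2))
  diag_good <- chain_diagnostics(good)
  expect_true(all(abs(diag_good$rhat - 1) < 0.02))
  expect_true(all(diag_good$ess <= 2000))

  # two offset halves: between-half variance far exceeds within
  bad <- fake_draws(cbind(c(rnorm(1000), rnorm(1000) + 3)))
  diag_bad <- chain_diagnostics(bad)
  expect_gt(max(diag_bad$rhat[grepl("loading1", diag_bad$parameter)]), 1.1)
})

test_that("retained draws export as one row per draw", {
  set.seed(59)
  d <- fake_draws(matrix(rnorm(600), 300, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws(d, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 300)
  expect_equal(ncol(tab), 5 * 2)
  expect_equal(tab$diff_1, d$diff[, 1])
})

test_that("the omnibus credibility decision detects a true loading gap", {
  samp <- make_sample(p = 5, n = 500, seed = 58, pct = 0.4)
  set.seed(6)
  tst <- bayes_invariance_test(samp, chain = reduced_chain())
  expect_true(tst$reject)
  flagged <- which(tst$decision$intervals$excludes_zero)
  expect_true(all(c(1, 2) %in% flagged))
})
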