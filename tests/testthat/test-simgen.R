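test_that("latent trait generator hits its moment targets", {
  set.seed(42)
  x <- draw_latent(1e6, latent_spec("normal"))
  expect_lt(abs(mean(x)), 0.01)
  expect_lt(abs(stats::var(x) - 1), 0.01)
  expect_lt(abs(skewness_of(x)), 0.01)

  # standardized gamma with shape k has skewness 2/sqrt(k): k = 1 -> 2,
  # k = 1/4 -> 4 (closed-form oracle)
  x2 <- draw_latent(1e6, latent_spec("skewed", 2))
  expect_lt(abs(mean(x2)), 0.01)
  expect_lt(abs(stats::var(x2) - 1), 0.02)
  expect_lt(abs(skewness_of(x2) - 2), 0.05)

  x4 <- draw_latent(1e6, latent_spec("skewed", 4))
  expect_lt(abs(skewness_of(x4) - 4), 0.10)
})

test_that("azzalini slant generator is standardized and right-skewed", {
  set.seed(43)
  x <- draw_latent(5e5, latent_spec("skewed", 2, generator = "azzalini_slant"))
  expect_lt(abs(mean(x)), 0.01)
  expect_lt(abs(stats::var(x) - 1), 0.01)
  expect_gt(skewness_of(x), 0.2)
  # the skew-normal moment skewness is bounded below 0.995
  expect_lt(skewness_of(x), 1)
})

test_that("latent spec validates its arguments", {
  expect_error(latent_spec("normal", skewness = 2), "skewness 0")
  expect_error(latent_spec("skewed", skewness = 0), "skewness > 0")
})

test_that("population model injects the documented non-invariance block", {
  pop <- build_population(null_condition(p = 10, pct = 0.20))
  expect_identical(pop$non_invariant_indices, 1:2)
  expect_equal(pop$loadings_g2, c(0.5, 0.5, rep(1, 8)))
  expect_equal(pop$loadings_g1, rep(1, 10))

  pop20 <- build_population(null_condition(p = 20, pct = 0.20))
  expect_length(pop20$non_invariant_indices, 4)

  pop0 <- build_population(null_condition(p = 10, pct = 0))
  expect_identical(pop0$loadings_g1, pop0$loadings_g2)
  expect_equal(pop0$intercepts, rep(0, 10))
  expect_equal(pop0$unique_sd, rep(1, 10))
})

test_that("generated indicators match the implied covariance closed form", {
  # lambda = 1 everywhere, psi = 1, theta = 1: diagonal 2, off-diagonal 1
  set.seed(7)
  pop <- build_population(null_condition(p = 4, pct = 0))
  n <- 1e6
  samp <- generate_sample(pop, n)
  S <- stats::cov(samp$group1)
  expect_lt(max(abs(S - (tcrossprod(rep(1, 4)) + diag(4)))), 0.012)
  expect_lt(max(abs(colMeans(samp$group1))), 0.01)

  # non-invariant indicator in group 2: lambda = 0.5 -> variance 1.25,
  # covariance 0.5 with a lambda = 1 indicator
  pop2 <- build_population(null_condition(p = 4, pct = 0.25))
  samp2 <- generate_sample(pop2, n)
  S2 <- stats::cov(samp2$group2)
  expect_lt(abs(S2[1, 1] - 1.25), 0.01)
  expect_lt(abs(S2[1, 2] - 0.5), 0.01)
  expect_lt(abs(S2[2, 2] - 2), 0.012)
})

test_that("generation is bit-reproducible from the seed", {
  s1 <- make_sample(p = 5, n = 50, seed = 99)
  s2 <- make_sample(p = 5, n = 50, seed = 99)
  expect_identical(s1$group1, s2$group1)
  expect_identical(s1$group2, s2$group2)
  s3 <- make_sample(p = 5, n = 50, seed = 100)
  expect_false(identical(s1$group1, s3$group1))
})

test_that("indicator skewness increases with latent skewness", {
  set.seed(11)
  sk <- vapply(c(0, 2, 4), function(s) {
    pop <- build_population(null_condition(p = 3, n = 100, skew = s))
    samp <- generate_sample(pop, 1e6)
    skewness_of(samp$group1[, 1])
  }, numeric(1))
  expect_true(all(diff(sk) > 0))
})

test_that("condition grid crosses all levels and excludes skew-t under normality", {
  grid <- condition_grid()
  expect_length(grid, 3 * 2 * 4 * 7)
  n_levels <- unique(vapply(grid, function(g) g$n_per_group, integer(1)))
  expect_length(n_levels, 7)
  fams <- vapply(grid, function(g) {
    if (g$latent$family == "normal") 0 else g$latent$skewness
  }, numeric(1))
  expect_setequal(unique(fams), c(0, 2, 4))
  for (g in grid) {
    m <- attr(g, "methods")
    if (g$latent$family == "normal") {
      expect_false("skewt" %in% m)
    } else {
      expect_true("skewt" %in% m)
    }
  }
  expect_error(condition_grid(skewness = numeric(0)), "at least one level")
})

test_that("samples round-trip through delimited text", {
  samp <- make_sample(p = 3, n = 20, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sample(samp, f)
  back <- read_indicator_table(f)
  expect_equal(back$group1, samp$group1, ignore_attr = TRUE)
  expect_equal(back$group2, samp$group2, ignore_attr = TRUE)
})
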