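# shared fixture builders for the test suite; everything is generated in code

null_condition <- function(p = 10, n = 100, skew = 0, pct = 0, reps = 200L) {
  spec <- if (skew == 0) latent_spec("normal") else latent_spec("skewed", skew)
  study_condition(spec, p = p, pct_non_invariant = pct, n_per_group = n,
                  reps = reps)
}

make_sample <- function(p = 10, n = 100, skew = 0, pct = 0, seed = 1) {
  set.seed(seed)
  generate_sample(build_population(null_condition(p, n, skew, pct)), n)
}

# sample skewness (third standardized moment)
skewness_of <- function(x) {
  z <- (x - mean(x)) / stats::sd(x)
  mean(z^3)
}

# hand-built posterior_draws object for exercising summaries and diagnostics
fake_draws <- function(diff_draws, p = ncol(diff_draws)) {
  l2 <- matrix(1, nrow(diff_draws), p)
  structure(list(loadings1 = l2 + diff_draws, loadings2 = l2,
                 intercepts = matrix(0, nrow(diff_draws), p),
                 uniquenesses = matrix(1, nrow(diff_draws), p),
                 diff = diff_draws, retained = nrow(diff_draws),
                 degenerate_draws = 0L,
                 chain = chain_spec(nrow(diff_draws), 0L, 1L),
                 priors = prior_spec(), n = c(100L, 100L), p = p),
            class = "posterior_draws")
}
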