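# invarsim

Monte Carlo comparison of procedures for testing **metric invariance** —
the equality of factor loadings across groups — in a two-group, one-factor
measurement model, with emphasis on small samples and skewed latent traits.

When a scale is used to compare people from different subgroups (boys and
girls, patients and controls), score comparisons are only meaningful if the
items relate to the latent trait the same way in every subgroup. The
standard check fits the common factor model

&nbsp;&nbsp;&nbsp;&nbsp;*x* = τ + Λξ + δ,&nbsp;&nbsp;&nbsp;&nbsp;Σ = ΛΨΛ′ + Θ

to both groups twice — once with loadings constrained equal, once free —
and compares fit. `invarsim` implements four such procedures end to end,
plus the simulation machinery to measure their Type I error, power, and
convergence behavior across a factorial grid of conditions:

| method | estimator | invariance decision |
|---|---|---|
| `ml` | normal-theory ML (MGCFA), F_ML = ln\|Σ\| − ln\|S\| + tr(SΣ⁻¹) − p | χ²-difference test, df = p |
| `skewt` | ML under the restricted multivariate skew-t (per-indicator skewness vector δ, df ν; p+1 extra parameters) | likelihood-ratio test, df = p |
| `bayes` | conjugate Gibbs sampler, flat normal priors on loadings/intercepts, diffuse inverse-gamma on unique variances | 95% credibility intervals of the per-indicator loading differences (Bonferroni-widened omnibus rule) |
| `gsca` | generalized structured component analysis (γ = wz, z = aγ + ε) by alternating least squares | AFIT = 1 − (1 − R̄²)·d₀/d₁ compared between models via a paired permutation-calibrated resampling test |

Synthetic data follow the study design: p ∈ {10, 20} indicators, loadings 1
(non-invariant group-2 loadings 0.5), intercepts 0, N(0,1) unique errors,
group sizes 25–1000, and a standardized latent trait that is normal or
skewed with third standardized moment 2 or 4 (moment-matched gamma by
default; an Azzalini-slant alternative is available).

## Worked example

Generate one dataset with 20% non-invariant loadings (indicators 1–2 have
group-2 loadings 0.5) at n = 200 per group, and test it with three methods:

```r
library(invarsim)
set.seed(42)
cond <- study_condition(latent_spec("normal"), p = 10,
                        pct_non_invariant = 0.2, n_per_group = 200)
samp <- generate_sample(build_population(cond), cond$n_per_group)

fit_c <- fit_mgcfa(samp, loadings_equal = TRUE)
fit_u <- fit_mgcfa(samp, loadings_equal = FALSE)
chisq_difference(fit_c, fit_u)
#> Chi-square difference test (normal-theory ML)
#>   statistic = 27.3930, df = 10, p = 0.002256 -> reject metric invariance at alpha = 0.05

fit_u
#> Two-group 1-factor ML fit (free loadings)
#>   T = 90.3901 on 80 df; converged: TRUE
#>   loadings group 1: 0.856 0.919 0.936 1.012 0.948 1.009 1.041 1.090 1.060 0.967
#>   loadings group 2: 0.502 0.601 0.985 0.939 1.045 0.989 1.137 0.877 0.997 1.125

set.seed(42)
afit_paired_test(samp, B = 100)
#> AFIT paired resampling test (GSCA)
#>   statistic = 2.6539, df = 99, p = 0.0198 -> reject metric invariance at alpha = 0.05

set.seed(42)
bayes_invariance_test(samp, chain = reduced_chain())$decision
#> Credibility-interval decision (95.0% level, multiplicity: bonferroni)
#>    indicator estimate    lower upper excludes_zero
#> 1         V1   0.3676  0.00246 0.736          TRUE
#> 2         V2   0.3281 -0.03248 0.627         FALSE
#> 3         V3  -0.0482 -0.41954 0.308         FALSE
#> ...
#> => reject metric invariance
```

All three procedures reject. The violation sits in the two indicators whose
group-2 loadings were generated at 0.5: the free ML fit estimates them at
0.50 and 0.60, and the posterior loading-difference intervals put the
largest gaps there (the first excluding 0 even after Bonferroni widening).

Monte Carlo cells and full grids run through the study harness:

```r
cell <- run_cell(study_condition(latent_spec("normal"), 10, 0, 200),
                 method = "ml", reps = 1000, seed = 1)
cell$rejection_rate          # empirical Type I error
bradley_in_control(cell$rejection_rate)

grid <- condition_grid(skewness = c(0, 2), n_per_group = c(50, 200))
report <- run_study(grid, methods = c("ml", "gsca"), reps = 200, seed = 1,
                    out_dir = "results/")
```

Applied users can test their own delimited table (indicators plus a `group`
column) with `test_invariance("data.csv", method = "ml")`. A thin
command-line harness lives at `inst/cli/simulate.R`.

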