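#' Specify the distribution of the latent trait
#'
#' Describes how latent trait scores are drawn for one simulated group. Two
#' skewing mechanisms are available. `"moment_matched_gamma"` draws from a
#' standardized gamma distribution whose shape is chosen so that the third
#' standardized moment equals `skewness` exactly (shape \eqn{k = 4/s^2} gives
#' skewness \eqn{2/\sqrt{k} = s}); this keeps the nominal skewness values a
#' directly testable population property. `"azzalini_slant"` instead draws from
#' a standardized skew-normal with slant parameter set to the nominal value;
#' its moment skewness is bounded by about 0.995, so the nominal value is then
#' a shape label rather than a moment target.
#'
#' @param family `"normal"` or `"skewed"`.
#' @param skewness Target third standardized moment of the latent trait.
#'   Must be 0 when `family = "normal"`; positive otherwise (the study grid
#'   uses 2 and 4).
#' @param generator Skewing mechanism, `"moment_matched_gamma"` (default) or
#'   `"azzalini_slant"`. Ignored for the normal family.
#' @return An object of class `"latent_spec"`.
#' @examples
#' latent_spec("skewed", skewness = 2)
#' @export
latent_spec <- function(family = c("normal", "skewed"), skewness = 0,
                        generator = c("moment_matched_gamma", "azzalini_slant")) {
  family <- match.arg(family)
  generator <- match.arg(generator)
  if (family == "normal" && skewness != 0) {
    stop("a normal latent trait has skewness 0", call. = FALSE)
  }
  if (family == "skewed" && skewness <= 0) {
    stop("a skewed latent trait needs skewness > 0", call. = FALSE)
  }
  structure(list(family = family, skewness = skewness, generator = generator),
            class = "latent_spec")
}

#' @export
print.latent_spec <- function(x, ...) {
  if (x$family == "normal") {
    cat("Latent trait: standard normal\n")
  } else {
    cat(sprintf("Latent trait: skewed (nominal skewness %g, generator %s)\n",
                x$skewness, x$generator))
  }
  invisible(x)
}

#' Draw latent trait scores
#'
#' Draws `n` values with population mean 0 and variance 1. Under the
#' moment-matched gamma generator the population third standardized moment
#' equals `spec$skewness`.
#'
#' @param n Number of draws (>= 1).
#' @param spec A [latent_spec()].
#' @return Numeric vector of length `n`.
#' @export
draw_latent <- function(n, spec) {
  stopifnot(inherits(spec, "latent_spec"), n >= 1)
  if (spec$family == "normal") {
    return(stats::rnorm(n))
  }
  switch(spec$generator,
    moment_matched_gamma = {
      k <- 4 / spec$skewness^2
      (stats::rgamma(n, shape = k, rate = 1) - k) / sqrt(k)
    },
    azzalini_slant = {
      # skew-normal via the hidden-truncation representation, standardized
      # to population mean 0, variance 1
      alpha <- spec$skewness
      d <- alpha / sqrt(1 + alpha^2)
      z0 <- abs(stats::rnorm(n))
      z1 <- stats::rnorm(n)
      x <- d * z0 + sqrt(1 - d^2) * z1
      mu <- d * sqrt(2 / pi)
      (x - mu) / sqrt(1 - mu^2)
    },
    stop("unknown latent-trait generator: ", spec$generator, call. = FALSE)
  )
}

#' Define one cell of the simulation design
#'
#' A study condition fixes the latent-trait distribution, the number of
#' indicators, the share of loadings that differ between the groups, and the
#' per-group sample size.
#'
#' @param latent A [latent_spec()].
#' @param p Number of indicators (the study grid uses 10 and 20).
#' @param pct_non_invariant Proportion of indicators whose group-2 loading is
#'   lowered to 0.5 (grid: 0, 0.10, 0.20, 0.30).
#' @param n_per_group Observations per group (grid: 25 to 1000).
#' @param reps Monte Carlo replications planned for the cell (default 1000).
#' @return An object of class `"study_condition"`.
#' @export
study_condition <- function(latent, p, pct_non_invariant, n_per_group,
                            reps = 1000L) {
  stopifnot(inherits(latent, "latent_spec"),
            p >= 2, pct_non_invariant >= 0, pct_non_invariant < 1,
            n_per_group >= 2, reps >= 1)
  structure(list(latent = latent, p = as.integer(p),
                 pct_non_invariant = pct_non_invariant,
                 n_per_group = as.integer(n_per_group),
                 reps = as.integer(reps)),
            class = "study_condition")
}

#' @export
print.study_condition <- function(x, ...) {
  cat(sprintf(
    "Study condition: p = %d, %.0f%% non-invariant, n = %d per group, %d reps\n",
    x$p, 100 * x$pct_non_invariant, x$n_per_group, x$reps))
  print(x$latent)
  invisible(x)
}

#' Build the two-group population model for a condition
#'
#' Group-1 loadings are all 1; in group 2 the first `round(pct * p)` indicators
#' have loading 0.5 (a gap of 0.5) and the rest 1. Intercepts are 0 and unique
#' error standard deviations 1 throughout. Which indicators carry the
#' non-invariance is exchangeable by symmetry of the design, so the leading
#' block is used.
#'
#' @param cond A [study_condition()].
#' @return An object of class `"population_model"` with fields `p`,
#'   `loadings_g1`, `loadings_g2`, `intercepts`, `unique_sd`, `latent` and
#'   `non_invariant_indices`.
#' @export
build_population <- function(cond) {
  stopifnot(inherits(cond, "study_condition"))
  p <- cond$p
  m <- as.integer(round(cond$pct_non_invariant * p))
  idx <- if (m > 0) seq_len(m) else integer(0)
  lam2 <- rep(1, p)
  lam2[idx] <- 0.5
  structure(list(p = p,
                 loadings_g1 = rep(1, p),
                 loadings_g2 = lam2,
                 intercepts = rep(0, p),
                 unique_sd = rep(1, p),
                 latent = cond$latent,
                 non_invariant_indices = idx),
            class = "population_model")
}

#' Generate a two-group sample from a population model
#'
#' Each indicator is `x = tau + lambda * xi + e` with `e ~ N(0, 1)` and the
#' latent trait `xi` drawn from the population's latent spec. Generation is
#' fully governed by R's RNG state, so `set.seed()` before the call makes the
#' tables reproducible bit for bit.
#'
#' @param pop A [build_population()] result.
#' @param n Observations per group (>= 2).
#' @return An object of class `"two_group_sample"`: a list with numeric
#'   matrices `group1` and `group2` (n x p, columns `V1..Vp`), the latent
#'   draws, and the generating population.
#' @export
generate_sample <- function(pop, n) {
  stopifnot(inherits(pop, "population_model"), n >= 2)
  p <- pop$p
  draw_group <- function(lam) {
    xi <- draw_latent(n, pop$latent)
    x <- tcrossprod(xi, lam) + matrix(stats::rnorm(n * p), n, p)
    x <- sweep(x, 2, pop$intercepts, "+")
    colnames(x) <- paste0("V", seq_len(p))
    list(x = x, xi = xi)
  }
  g1 <- draw_group(pop$loadings_g1)
  g2 <- draw_group(pop$loadings_g2)
  structure(list(group1 = g1$x, group2 = g2$x,
                 latent1 = g1$xi, latent2 = g2$xi,
                 population = pop),
            class = "two_group_sample")
}

#' @export
print.two_group_sample <- function(x, ...) {
  cat(sprintf("Two-group sample: %d + %d observations, %d indicators\n",
              nrow(x$group1), nrow(x$group2), ncol(x$group1)))
  invisible(x)
}

#' Enumerate the crossed condition grid
#'
#' Fully crosses the supplied factor levels. The default levels are the study
#' grid: three latent-trait distributions (normal, skewness 2, skewness 4),
#' 10 or 20 indicators, 0/10/20/30% non-invariant loadings, and seven group
#' sizes from 25 to 1000 - 168 conditions. Each condition carries the list of
#' estimation methods allowed for it: the skew-t estimator is never paired
#' with the normal latent trait.
#'
#' @param skewness Latent-trait skewness levels (0 means normal).
#' @param p Indicator-count levels.
#' @param pct_non_invariant Non-invariance proportion levels.
#' @param n_per_group Group-size levels.
#' @param reps Replications per cell.
#' @param generator Skewing mechanism passed to [latent_spec()].
#' @param methods Candidate estimation methods.
#' @return A list of `"study_condition"` objects, each with a `methods`
#'   attribute.
#' @export
condition_grid <- function(skewness = c(0, 2, 4),
                           p = c(10L, 20L),
                           pct_non_invariant = c(0, 0.10, 0.20, 0.30),
                           n_per_group = c(25L, 50L, 75L, 100L, 200L, 500L, 1000L),
                           reps = 1000L,
                           generator = "moment_matched_gamma",
                           methods = c("ml", "skewt", "bayes", "gsca")) {
  if (length(skewness) == 0 || length(p) == 0 ||
      length(pct_non_invariant) == 0 || length(n_per_group) == 0) {
    stop("every design factor needs at least one level", call. = FALSE)
  }
  levels <- expand.grid(skewness = skewness, p = p,
                        pct = pct_non_invariant, n = n_per_group,
                        KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(levels))
  for (i in seq_len(nrow(levels))) {
    s <- levels$skewness[i]
    spec <- if (s == 0) latent_spec("normal") else {
      latent_spec("skewed", skewness = s, generator = generator)
    }
    cond <- study_condition(spec, levels$p[i], levels$pct[i], levels$n[i],
                            reps = reps)
    allowed <- methods
    if (spec$family == "normal") allowed <- setdiff(allowed, "skewt")
    attr(cond, "methods") <- allowed
    out[[i]] <- cond
  }
  out
}

#' Write a two-group sample as a delimited text table
#'
#' Rows from both groups are stacked with a `group` column (1 or 2) appended
#' after the indicator columns.
#'
#' @param sample A `"two_group_sample"`.
#' @param file Path to write to.
#' @param sep Field separator (default comma).
#' @export
write_sample <- function(sample, file, sep = ",") {
  stopifnot(inherits(sample, "two_group_sample"))
  tab <- rbind(
    data.frame(sample$group1, group = 1L, check.names = FALSE),
    data.frame(sample$group2, group = 2L, check.names = FALSE)
  )
  utils::write.table(tab, file = file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read an indicator table with a group column
#'
#' Applied-mode input: a delimited numeric table of observations by indicators
#' plus one column identifying the group. Exactly two groups are expected.
#'
#' @param file Path to a delimited text file with a header row.
#' @param group_col Name of the group column (default `"group"`).
#' @param sep Field separator (default comma).
#' @return A `"two_group_sample"` (without population provenance).
#' @export
read_indicator_table <- function(file, group_col = "group", sep = ",") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (!group_col %in% names(tab)) {
    stop("no column named '", group_col, "' in ", file, call. = FALSE)
  }
  as_two_group_sample(tab[, setdiff(names(tab), group_col), drop = FALSE],
                      tab[[group_col]])
}

#' Assemble a two-group sample from a data frame and group labels
#'
#' @param data Numeric data frame or matrix (observations x indicators).
#' @param group Vector with exactly two distinct values; the first level in
#'   sort order becomes group 1.
#' @return A `"two_group_sample"`.
#' @export
as_two_group_sample <- function(data, group) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("indicator columns must be numeric", call. = FALSE)
  if (anyNA(x)) stop("missing values are not supported", call. = FALSE)
  g <- sort(unique(group))
  if (length(g) != 2) stop("exactly two groups are required", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  structure(list(group1 = x[group == g[1], , drop = FALSE],
                 group2 = x[group == g[2], , drop = FALSE],
                 latent1 = NULL, latent2 = NULL, population = NULL),
            class = "two_group_sample")
}
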