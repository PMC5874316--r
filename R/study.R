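#' Bradley's liberal robustness criterion
#'
#' An empirical Type I error rate at nominal level 0.05 is "under control"
#' when it lies in the closed interval [0.025, 0.075]. Both endpoints count as
#' in control.
#'
#' @param rate Proportion(s) in [0, 1].
#' @return Logical vector.
#' @examples
#' bradley_in_control(c(0.05, 0.076, 0.025))
#' @export
bradley_in_control <- function(rate) {
  stopifnot(all(rate >= 0 & rate <= 1, na.rm = TRUE))
  rate >= 0.025 & rate <= 0.075
}

# deterministic per-replication seed below 2^31, derived from the master
# seed, the cell index and the replication index so that cells are
# independent, order-free work units
rep_seed <- function(seed, cell_id, rep) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(cell_id) * 7919 +
                as.numeric(rep) * 104729) %% 2147483629)
}

# one replication of one method on one condition; returns reject / converged
run_one_rep <- function(cond, method, bayes_chain, priors, B, alpha,
                        multiplicity) {
  pop <- build_population(cond)
  samp <- generate_sample(pop, cond$n_per_group)
  switch(method,
    ml = {
      fit_c <- suppressWarnings(fit_mgcfa(samp, loadings_equal = TRUE))
      fit_u <- suppressWarnings(fit_mgcfa(samp, loadings_equal = FALSE))
      if (!fit_c$converged || !fit_u$converged) {
        list(converged = FALSE, reject = NA)
      } else {
        tst <- chisq_difference(fit_c, fit_u, alpha = alpha)
        list(converged = TRUE, reject = tst$reject)
      }
    },
    skewt = {
      fit_c <- fit_skewt_mgcfa(samp, loadings_equal = TRUE)
      fit_u <- fit_skewt_mgcfa(samp, loadings_equal = FALSE)
      if (!fit_c$converged || !fit_u$converged ||
          2 * (fit_u$loglik - fit_c$loglik) < -1e-6) {
        list(converged = FALSE, reject = NA)
      } else {
        tst <- skewt_invariance_test(fit_c, fit_u, alpha = alpha)
        list(converged = TRUE, reject = tst$reject)
      }
    },
    bayes = {
      tst <- bayes_invariance_test(samp, chain = bayes_chain, priors = priors,
                                   level = 1 - alpha,
                                   multiplicity = multiplicity)
      list(converged = TRUE, reject = tst$reject)
    },
    gsca = {
      tst <- afit_paired_test(samp, B = B, alpha = alpha)
      list(converged = isTRUE(tst$converged), reject = tst$reject)
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Run all replications of one method in one design cell
#'
#' Generates `reps` independent two-group samples under the condition, applies
#' the chosen invariance test to each, and aggregates the rejection rate
#' (over converged replications only; non-converged replications are recorded
#' in the convergence rate but excluded from the rejection denominator) and
#' the convergence rate. Each replication re-seeds R's RNG from
#' `(seed, cell_id, rep)`, so a cell is reproducible in isolation and
#' independent of execution order.
#'
#' For `pct_non_invariant = 0` the rejection rate estimates Type I error; for
#' positive percentages it estimates power.
#'
#' @param cond A [study_condition()].
#' @param method One of `"ml"`, `"skewt"`, `"bayes"`, `"gsca"`. The skew-t
#'   estimator is not allowed on normal-trait conditions.
#' @param reps Number of replications (default: the condition's `reps`).
#' @param seed Master integer seed.
#' @param cell_id Integer index of the cell within a study (default 1).
#' @param bayes_chain Chain settings for the Bayes method (default
#'   [reduced_chain()]).
#' @param priors Priors for the Bayes method.
#' @param B Bootstrap resamples for the GSCA test.
#' @param alpha Test level.
#' @param multiplicity Interval-widening rule for the Bayes decision
#'   (default `"bonferroni"`; see [summarize_differences()]).
#' @return An object of class `"cell_result"`.
#' @export
run_cell <- function(cond, method, reps = cond$reps, seed = 1L, cell_id = 1L,
                     bayes_chain = reduced_chain(), priors = prior_spec(),
                     B = 100L, alpha = 0.05, multiplicity = "bonferroni") {
  stopifnot(inherits(cond, "study_condition"))
  method <- match.arg(method, c("ml", "skewt", "bayes", "gsca"))
  if (method == "skewt" && cond$latent$family == "normal") {
    stop("the skew-t estimator is not paired with a normal latent trait",
         call. = FALSE)
  }
  n_conv <- 0L; n_rej <- 0L; n_err <- 0L
  for (r in seq_len(reps)) {
    set.seed(rep_seed(seed, cell_id, r))
    res <- tryCatch(
      run_one_rep(cond, method, bayes_chain, priors, B, alpha, multiplicity),
      error = function(e) list(converged = FALSE, reject = NA, error = TRUE))
    if (isTRUE(res$error)) n_err <- n_err + 1L
    if (isTRUE(res$converged)) {
      n_conv <- n_conv + 1L
      if (isTRUE(res$reject)) n_rej <- n_rej + 1L
    }
  }
  structure(list(condition = cond, method = method,
                 reps = reps,
                 n_converged = n_conv,
                 n_rejected = n_rej,
                 n_errors = n_err,
                 rejection_rate = if (n_conv > 0) n_rej / n_conv else NA_real_,
                 convergence_rate = n_conv / reps,
                 seed = seed, cell_id = cell_id),
            class = "cell_result")
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf("Cell result [%s]: rejection %.3f (n = %d converged / %d reps)\n",
              x$method, x$rejection_rate, x$n_converged, x$reps))
  invisible(x)
}

#' @export
as.data.frame.cell_result <- function(x, ...) {
  cond <- x$condition
  data.frame(method = x$method,
             distribution = if (cond$latent$family == "normal") "normal"
                            else paste0("skew", cond$latent$skewness),
             skewness = cond$latent$skewness,
             p = cond$p,
             pct_non_invariant = cond$pct_non_invariant,
             n_per_group = cond$n_per_group,
             reps = x$reps,
             n_converged = x$n_converged,
             rejection_rate = x$rejection_rate,
             convergence_rate = x$convergence_rate,
             bradley_in_control = if (cond$pct_non_invariant == 0)
               bradley_in_control(x$rejection_rate) else NA,
             cell_id = x$cell_id,
             stringsAsFactors = FALSE)
}

#' Eta-squared ANOVA screen over cell rates
#'
#' Fits a factorial ANOVA with the per-cell rejection rates as the response
#' and the manipulated design factors (and their interactions) as terms, and
#' computes each term's effect size \eqn{\eta^2 = SS_{term}/SS_{total}}. A
#' term is flagged for further inspection when its F-test is significant and
#' \eqn{\eta^2 \ge 0.1} (at least 10% of the rate variance). In a saturated
#' model the residual degrees of freedom are zero, so F and its p-value are
#' undefined (`NA`) while the eta-squared values are still reported.
#'
#' @param cell_table Data frame with one rate per cell (e.g. from
#'   [run_study()]).
#' @param formula Model formula, e.g. `rejection_rate ~ method * p *
#'   n_per_group`. Right-hand-side variables are coerced to factors.
#' @param threshold Eta-squared flag threshold (default 0.1).
#' @param alpha Significance level for the F screen (default 0.05).
#' @param transform `"none"` (raw proportions, the default) or
#'   `"asinsqrt"` (arcsine-square-root variance stabilization).
#' @return Data frame with columns `term`, `df`, `ss`, `F`, `p_value`,
#'   `eta_sq`, `flag`.
#' @export
eta_squared_screen <- function(cell_table, formula, threshold = 0.1,
                               alpha = 0.05,
                               transform = c("none", "asinsqrt")) {
  transform <- match.arg(transform)
  dat <- as.data.frame(cell_table)
  vars <- all.vars(formula)
  response <- vars[1]
  for (v in vars[-1]) dat[[v]] <- factor(dat[[v]])
  dat <- dat[!is.na(dat[[response]]), , drop = FALSE]
  if (transform == "asinsqrt") {
    dat[[response]] <- asin(sqrt(pmin(pmax(dat[[response]], 0), 1)))
  }
  fit <- stats::aov(formula, data = dat)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  ss_total <- sum(tab[["Sum Sq"]])
  resid <- term == "Residuals"
  out <- data.frame(term = term[!resid],
                    df = tab[["Df"]][!resid],
                    ss = tab[["Sum Sq"]][!resid],
                    F = if ("F value" %in% names(tab)) tab[["F value"]][!resid]
                        else NA_real_,
                    p_value = if ("Pr(>F)" %in% names(tab)) tab[["Pr(>F)"]][!resid]
                              else NA_real_,
                    eta_sq = if (ss_total > 1e-20)
                               tab[["Sum Sq"]][!resid] / ss_total
                             else rep(0, sum(!resid)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$flag <- !is.na(out$p_value) & out$p_value < alpha &
    out$eta_sq >= threshold
  out
}

#' Run the full Monte Carlo study
#'
#' Executes every (condition, method) pair of the grid through [run_cell()],
#' stacks the cell results, applies Bradley's criterion to the null
#' (Type I error) cells, and screens the Type I error and power tables with
#' separate eta-squared ANOVAs (method by indicator count by group size by
#' distribution, plus the non-invariance percentage for power). Cells are
#' independent work units with per-cell RNG substreams, so results are
#' identical however the loop is chunked.
#'
#' @param grid List of conditions from [condition_grid()].
#' @param methods Methods to run (intersected with each condition's allowed
#'   set).
#' @param reps Replications per cell (default: each condition's own `reps`).
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, `cells.csv`,
#'   `anova_type1.csv`, `anova_power.csv` and `run_log.txt` are written there.
#' @param bayes_chain,priors,B,alpha,multiplicity Passed to [run_cell()].
#' @param workers Number of parallel worker processes (forked via the
#'   parallel package). Cells are independent work units whose RNG substreams
#'   depend only on `(seed, cell_id, rep)`, so results are identical for any
#'   worker count.
#' @param verbose Print one line per completed cell?
#' @return An object of class `"study_report"`: `cells` (data frame),
#'   `anova_type1`, `anova_power`, `seed`, `methods`.
#' @export
run_study <- function(grid, methods = c("ml", "skewt", "bayes", "gsca"),
                      reps = NULL, seed = 1L, out_dir = NULL,
                      bayes_chain = reduced_chain(), priors = prior_spec(),
                      B = 100L, alpha = 0.05, multiplicity = "bonferroni",
                      workers = 1L, verbose = FALSE) {
  stopifnot(length(grid) >= 1)
  units <- list()
  k <- 0L
  for (i in seq_along(grid)) {
    cond <- grid[[i]]
    allowed <- intersect(methods, attr(cond, "methods") %||%
                           c("ml", "skewt", "bayes", "gsca"))
    if (cond$latent$family == "normal") allowed <- setdiff(allowed, "skewt")
    for (m in allowed) {
      k <- k + 1L
      units[[k]] <- list(cond = cond, method = m, cell_id = k)
    }
  }
  run_unit <- function(u) {
    cell <- tryCatch(
      run_cell(u$cond, u$method,
               reps = if (is.null(reps)) u$cond$reps else reps,
               seed = seed, cell_id = u$cell_id, bayes_chain = bayes_chain,
               priors = priors, B = B, alpha = alpha,
               multiplicity = multiplicity),
      error = function(e) e)
    if (inherits(cell, "error")) {
      row <- as.data.frame(run_cell(u$cond, u$method, reps = 0L, seed = seed,
                                    cell_id = u$cell_id))
      row$failed <- TRUE
    } else {
      row <- as.data.frame(cell)
      row$failed <- FALSE
    }
    if (verbose) {
      cat(sprintf("cell %d: %s p=%d pct=%.2f n=%d -> rate %.3f\n",
                  u$cell_id, row$method, row$p, row$pct_non_invariant,
                  row$n_per_group, row$rejection_rate))
    }
    row
  }
  rows <- if (workers > 1L) {
    parallel::mclapply(units, run_unit, mc.cores = workers)
  } else {
    lapply(units, run_unit)
  }
  cells <- do.call(rbind, rows)
  screen <- function(dat, power) {
    if (nrow(dat) < 4) return(NULL)
    keep <- c("method", "p", "n_per_group", "skewness",
              if (power) "pct_non_invariant")
    keep <- keep[vapply(keep, function(v) length(unique(dat[[v]])) > 1,
                        logical(1))]
    if (length(keep) == 0) return(NULL)
    f <- stats::as.formula(paste("rejection_rate ~",
                                 paste(keep, collapse = " * ")))
    tryCatch(eta_squared_screen(dat, f), error = function(e) NULL)
  }
  type1 <- cells[cells$pct_non_invariant == 0, , drop = FALSE]
  power <- cells[cells$pct_non_invariant > 0, , drop = FALSE]
  report <- structure(list(cells = cells,
                           anova_type1 = screen(type1, power = FALSE),
                           anova_power = screen(power, power = TRUE),
                           seed = seed, methods = methods,
                           bayes_chain = bayes_chain, B = B, alpha = alpha),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    if (!is.null(report$anova_type1)) {
      utils::write.csv(report$anova_type1,
                       file.path(out_dir, "anova_type1.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$anova_power)) {
      utils::write.csv(report$anova_power,
                       file.path(out_dir, "anova_power.csv"),
                       row.names = FALSE)
    }
    writeLines(c(sprintf("seed: %d", seed),
                 sprintf("methods: %s", paste(methods, collapse = ",")),
                 sprintf("cells: %d", nrow(cells)),
                 sprintf("bayes chain: post %d burn %d thin %d",
                         bayes_chain$post, bayes_chain$burn,
                         bayes_chain$thin),
                 sprintf("gsca bootstrap B: %d", B),
                 sprintf("date: %s", format(Sys.time()))),
               file.path(out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d cell x method rows (seed %d)\n",
              nrow(x$cells), x$seed))
  t1 <- x$cells[x$cells$pct_non_invariant == 0, ]
  if (nrow(t1) > 0) {
    cat(sprintf("  Type I error cells: %d (%d in Bradley band)\n",
                nrow(t1), sum(t1$bradley_in_control, na.rm = TRUE)))
  }
  pw <- x$cells[x$cells$pct_non_invariant > 0, ]
  if (nrow(pw) > 0) {
    cat(sprintf("  Power cells: %d (mean power %.3f)\n",
                nrow(pw), mean(pw$rejection_rate, na.rm = TRUE)))
  }
  invisible(x)
}

#' Applied-mode metric invariance test on a data table
#'
#' Runs a chosen invariance test on user data (observations by indicators
#' plus a group column) and, optionally, writes a small CSV report of the
#' key quantities.
#'
#' @param data Numeric data frame or matrix of indicators, or a path to a
#'   delimited file readable by [read_indicator_table()].
#' @param group Group labels (ignored when `data` is a file path with its own
#'   group column).
#' @param method `"ml"`, `"skewt"`, `"bayes"` or `"gsca"`.
#' @param alpha Test level.
#' @param report Optional path for a CSV report.
#' @param ... Method-specific settings passed on (e.g. `chain`, `B`).
#' @return A list with the fitted objects and the `"invariance_test"`.
#' @export
test_invariance <- function(data, group = NULL,
                            method = c("ml", "skewt", "bayes", "gsca"),
                            alpha = 0.05, report = NULL, ...) {
  method <- match.arg(method)
  samp <- if (is.character(data) && length(data) == 1) {
    read_indicator_table(data)
  } else {
    as_two_group_sample(data, group)
  }
  out <- switch(method,
    ml = {
      fit_c <- fit_mgcfa(samp, loadings_equal = TRUE)
      fit_u <- fit_mgcfa(samp, loadings_equal = FALSE)
      list(fit_constrained = fit_c, fit_unconstrained = fit_u,
           test = chisq_difference(fit_c, fit_u, alpha = alpha))
    },
    skewt = {
      fit_c <- fit_skewt_mgcfa(samp, loadings_equal = TRUE, ...)
      fit_u <- fit_skewt_mgcfa(samp, loadings_equal = FALSE, ...)
      list(fit_constrained = fit_c, fit_unconstrained = fit_u,
           test = skewt_invariance_test(fit_c, fit_u, alpha = alpha))
    },
    bayes = {
      tst <- bayes_invariance_test(samp, level = 1 - alpha, ...)
      list(test = tst, decision = tst$decision)
    },
    gsca = {
      tst <- afit_paired_test(samp, alpha = alpha, ...)
      list(fit_constrained = fit_gsca(samp, constrained = TRUE),
           fit_unconstrained = fit_gsca(samp, constrained = FALSE),
           test = tst)
    })
  if (!is.null(report)) {
    tst <- out$test
    tab <- data.frame(method = method,
                      statistic = tst$statistic,
                      df = tst$df,
                      p_value = tst$p_value,
                      reject = tst$reject)
    if (method == "skewt") {
      tab$nu <- out$fit_unconstrained$nu
      tab$mean_abs_skew <- mean(abs(out$fit_unconstrained$delta))
    }
    utils::write.csv(tab, report, row.names = FALSE)
  }
  out
}
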