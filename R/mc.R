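# Monte Carlo evaluation harness: repeated simulation + reconstruction,
# summarized by median relative bias of total annual abundance and by the
# aggregate coverage of the asymptotic 95% confidence intervals.

#' Median relative bias of abundance estimates
#'
#' Per year, the median over replicates of `100 * (estimate - truth) /
#' truth` (in percent).
#'
#' @param estimates replicates x years matrix of estimated total abundance.
#' @param truth matching matrix (or a single-year vector) of true abundance.
#' @return Per-year median relative bias, in percentage points.
#' @export
median_relative_bias <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  truth <- as.matrix(truth)
  stopifnot(all(dim(estimates) == dim(truth)))
  if (any(truth == 0)) stop("true abundance of zero: relative bias undefined")
  rb <- 100 * (estimates - truth) / truth
  apply(rb, 2L, stats::median, na.rm = TRUE)
}

#' Aggregate 95% confidence interval coverage
#'
#' The fraction of (replicate, year) pairs whose interval contains the true
#' abundance, aggregated across years and replicates.
#'
#' @param lower,upper replicates x years matrices of interval limits.
#' @param truth matching matrix of true abundance.
#' @return Proportion in `[0, 1]`.
#' @export
ci_coverage <- function(lower, upper, truth) {
  lower <- as.matrix(lower); upper <- as.matrix(upper)
  truth <- as.matrix(truth)
  stopifnot(all(dim(lower) == dim(truth)), all(dim(upper) == dim(truth)))
  hit <- truth >= lower & truth <= upper
  mean(hit, na.rm = TRUE)
}

#' Run one cell of the Monte Carlo performance study
#'
#' Simulates `n_reps` populations under one set of study conditions, fits
#' the requested model to each, and collects the per-year abundance
#' estimates, interval limits and truths.  Replicates whose fit fails or
#' does not converge are excluded and counted.
#'
#' @param spec an [model_spec()].
#' @param sigma common interannual standard deviation.
#' @param telemetry_years 1 or 6.
#' @param scenario simulator scenario.
#' @param n_reps number of replicates.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param control passed to [fit_spr()].
#' @return List with matrices `estimate`, `lcl`, `ucl`, `truth`
#'   (converged replicates only) and the count `n_failed`.
#' @export
mc_cell <- function(spec, sigma = 0, telemetry_years = 6L,
                    scenario = "baseline", n_reps = 100L, seed = 1L,
                    control = list()) {
  res <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(sigma = sigma, telemetry_years = telemetry_years,
                      scenario = scenario, seed = seed + r)
    fit <- tryCatch(suppressWarnings({
      pop <- simulate_population(cfg)
      fit_spr(pop$aah, pop$telemetry, spec, control = control)
    }), error = function(e) NULL)
    ok <- !is.null(fit) && isTRUE(fit$converged) &&
      all(is.finite(fit$abundance$estimate))
    if (!ok) {
      n_failed <- n_failed + 1L
      next
    }
    res[[r]] <- list(est = fit$abundance$estimate, lcl = fit$abundance$lcl,
                     ucl = fit$abundance$ucl, truth = pop$truth$total)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) stop("no replicate produced a converged fit")
  list(
    estimate = do.call(rbind, lapply(res, `[[`, "est")),
    lcl = do.call(rbind, lapply(res, `[[`, "lcl")),
    ucl = do.call(rbind, lapply(res, `[[`, "ucl")),
    truth = do.call(rbind, lapply(res, `[[`, "truth")),
    n_failed = n_failed
  )
}

#' Monte Carlo study over a grid of conditions
#'
#' Evaluates each combination of model, variation level, telemetry design,
#' catch-effort usage and scenario, reporting the across-year mean of the
#' per-year median relative bias, the aggregate 95% CI coverage, and the
#' number of failed fits.  Per-year median-relative-bias vectors are
#' attached as the `per_year` attribute.
#'
#' @param models list of [model_spec()] objects.
#' @param sigma_levels numeric vector of variation levels.
#' @param telemetry_designs integer vector from {1, 6}.
#' @param scenarios character vector of simulator scenarios.
#' @param n_reps replicates per cell.
#' @param seed master seed.
#' @param control passed to [fit_spr()].
#' @return Data frame with one row per grid cell.
#' @export
run_mc_study <- function(models = list(model_spec("HT", "RE")),
                         sigma_levels = c(0, 0.1, 0.2, 0.3),
                         telemetry_designs = 6L, scenarios = "baseline",
                         n_reps = 100L, seed = 1L, control = list()) {
  rows <- list()
  per_year <- list()
  for (m in seq_along(models)) {
    for (sg in sigma_levels) {
      for (td in telemetry_designs) {
        for (sc in scenarios) {
          cell <- mc_cell(models[[m]], sigma = sg, telemetry_years = td,
                          scenario = sc, n_reps = n_reps, seed = seed,
                          control = control)
          mrb <- median_relative_bias(cell$estimate, cell$truth)
          cov <- ci_coverage(cell$lcl, cell$ucl, cell$truth)
          key <- paste(model_code(models[[m]]),
                       if (models[[m]]$catch_effort) "CE" else "noCE",
                       sg, td, sc, sep = "_")
          rows[[key]] <- data.frame(
            model = model_code(models[[m]]),
            catch_effort = models[[m]]$catch_effort, sigma = sg,
            telemetry_years = td, scenario = sc,
            n_reps = n_reps, n_failed = cell$n_failed,
            mean_mrb = mean(mrb), coverage = cov)
          per_year[[key]] <- mrb
        }
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "per_year") <- per_year
  out
}
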