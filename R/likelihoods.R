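# Likelihood components for statistical population reconstruction.
#
# The conditional age-at-harvest likelihood treats the cells of the harvest
# matrix as a multinomial sample, conditional on the total number of animals
# ever harvested, with cell probabilities proportional to the expected counts
# of the cohort recursion.  By the chain rule this single multinomial is the
# product of the sequential per-cohort conditional binomials, so it is the
# "product of individual cohort likelihoods" in one proper factorization even
# though the pooled adult class makes per-cohort adult counts unobservable.

NEG_INF_SENTINEL <- -1e10

#' Conditional cell probabilities from expected counts
#'
#' Normalizes a vector of expected harvest counts into the conditional
#' probabilities that an ever-harvested animal falls in each cell.
#'
#' @param expected non-negative expected counts with a positive sum.
#' @return Probabilities summing to 1.
#' @examples
#' conditional_cell_probs(c(400, 120, 36))
#' @export
conditional_cell_probs <- function(expected) {
  if (any(!is.finite(expected)) || any(expected < 0)) {
    stop("expected counts must be finite and non-negative")
  }
  tot <- sum(expected)
  if (tot <= 0) stop("degenerate cohort: total expected harvest is zero")
  expected / tot
}

#' Conditional multinomial log-likelihood of harvest cells
#'
#' Multinomial log-likelihood of the observed cell counts given the total
#' (the conditional-on-harvest cohort likelihood).  The combinatorial
#' constant is retained so that AIC values are comparable across models.
#' A cell with zero probability but a positive count yields a large negative
#' sentinel (with a warning) rather than `-Inf`, so optimizers can recover.
#'
#' @param x observed counts (may be fractional under continuous relaxation).
#' @param probs cell probabilities summing to 1.
#' @return Log-likelihood value.
#' @examples
#' cohort_loglik(c(1, 1), c(0.5, 0.5))  # log(0.5)
#' @export
cohort_loglik <- function(x, probs) {
  stopifnot(length(x) == length(probs))
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("probs must be a probability vector")
  }
  bad <- probs == 0 & x > 0
  if (any(bad)) {
    warning("observed harvest in a cell with zero probability; ",
            "returning sentinel log-likelihood")
    return(NEG_INF_SENTINEL)
  }
  keep <- x > 0
  lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x[keep] * log(probs[keep]))
}

#' Binomial log-likelihood of an edge cohort
#'
#' The first cohort (adults present at study initiation) and the last
#' (final-year juveniles) have no within-cohort timing information, so they
#' enter the likelihood as plain binomial components: harvested versus
#' not-harvested out of the cohort's entry abundance.  Continuous (HT or
#' estimated) abundances are handled through the gamma-function form of the
#' binomial coefficient.
#'
#' @param x observed harvest count at the cohort's entry cell.
#' @param size cohort entry abundance (may be non-integer).
#' @param prob harvest probability at the entry cell.
#' @return Log-likelihood value (sentinel for impossible configurations).
#' @export
edge_cohort_loglik <- function(x, size, prob) {
  stopifnot(length(x) == 1L, length(size) == 1L, length(prob) == 1L)
  if (x < 0 || size < 0) stop("counts must be non-negative")
  if (prob < 0 || prob > 1) stop("prob must lie in [0, 1]")
  if (size < x || (prob == 0 && x > 0) || (prob == 1 && size > x)) {
    warning("impossible edge-cohort configuration; returning sentinel")
    return(NEG_INF_SENTINEL)
  }
  lgamma(size + 1) - lgamma(x + 1) - lgamma(size - x + 1) +
    (if (x > 0) x * log(prob) else 0) +
    (if (size > x) (size - x) * log1p(-prob) else 0)
}

#' Radiotelemetry binomial log-likelihood
#'
#' Sums binomial log-probabilities of the number of tagged animals harvested
#' out of those at risk, with the harvest probability of untagged animals.
#'
#' @param telemetry a [telemetry_data()] object.
#' @param P data frame with columns `year`, `age_class`, `prob` giving the
#'   harvest probability for every telemetry year and age class.
#' @return Log-likelihood value (0 for empty telemetry).
#' @export
telemetry_loglik <- function(telemetry, P) {
  stopifnot(inherits(telemetry, "telemetry_data"))
  if (nrow(telemetry) == 0L) return(0)
  ll <- 0
  for (k in seq_len(nrow(telemetry))) {
    m <- telemetry$n_at_risk[k]
    y <- telemetry$n_harvested[k]
    idx <- which(P$year == telemetry$year[k] &
                   P$age_class == telemetry$age_class[k])
    if (length(idx) != 1L) {
      stop("no harvest probability for telemetry year ", telemetry$year[k],
           ", class ", telemetry$age_class[k])
    }
    p <- P$prob[idx]
    if (m == 0L) next
    if ((p == 0 && y > 0) || (p == 1 && y < m)) {
      warning("telemetry record impossible under P; returning sentinel")
      return(NEG_INF_SENTINEL)
    }
    ll <- ll + stats::dbinom(y, m, p, log = TRUE)
  }
  ll
}

#' Auxiliary catch-effort log-likelihood
#'
#' Treats each year's total harvest as a binomial sample from that year's
#' (rounded) total abundance with the pooled harvest probability.  Under the
#' Horvitz-Thompson models the abundance is the current second-stage estimate
#' plugged in as data, in the spirit of an EM step.
#'
#' @param total_harvest per-year total harvest counts.
#' @param N_total per-year total abundance (rounded to integers internally).
#' @param P per-year pooled harvest probability.
#' @return Log-likelihood value (sentinel when any `N_total < harvest`).
#' @export
catch_effort_loglik <- function(total_harvest, N_total, P) {
  stopifnot(length(total_harvest) == length(N_total),
            length(N_total) == length(P))
  N <- round(N_total)
  if (any(N < total_harvest)) {
    warning("catch-effort abundance below observed harvest; sentinel")
    return(NEG_INF_SENTINEL)
  }
  sum(stats::dbinom(total_harvest, N, P, log = TRUE))
}

#' Normal random-effects penalty
#'
#' The joint likelihood is augmented with independent mean-zero normal
#' densities for the annual survival effects `delta` and vulnerability
#' effects `nu`.  Pass `NULL` for a process with no random effects (the
#' fixed-effects model has penalty 0).
#'
#' @param delta,nu random-effect vectors or `NULL`.
#' @param sigma_s,sigma_c standard deviations (must be positive when the
#'   corresponding effect vector is non-empty).
#' @return Sum of log densities.
#' @export
re_penalty <- function(delta = NULL, nu = NULL, sigma_s = NULL,
                       sigma_c = NULL) {
  ll <- 0
  if (!is.null(delta) && length(delta)) {
    if (is.null(sigma_s) || sigma_s <= 0) {
      stop("sigma_s must be positive when survival effects are present")
    }
    ll <- ll + sum(stats::dnorm(delta, 0, sigma_s, log = TRUE))
  }
  if (!is.null(nu) && length(nu)) {
    if (is.null(sigma_c) || sigma_c <= 0) {
      stop("sigma_c must be positive when vulnerability effects are present")
    }
    ll <- ll + sum(stats::dnorm(nu, 0, sigma_c, log = TRUE))
  }
  ll
}

#' Joint negative log-likelihood of the small-game model (reference path)
#'
#' Pure-R assembly of all likelihood components: the conditional multinomial
#' over the Y x 2 harvest cells, the two edge-cohort binomials, the
#' radiotelemetry likelihood, the optional catch-effort auxiliary, and the
#' random-effects penalty.  This is the reference implementation used for
#' testing and for the generic Laplace routine; [fit_spr()] evaluates the
#' same objective through its compiled template.
#'
#' @param par list with elements `s_base`, `c_base`, `sigma_s`, `sigma_c`,
#'   `delta` (length Y), `nu` (length Y).
#' @param data an [aah_data()] object.
#' @param telemetry a [telemetry_data()] object (pooled age class).
#' @param spec an [model_spec()] object.
#' @param entry_abundance per-cohort entry abundances (length Y + 1): HT
#'   plug-in estimates, or current parameter values for AA models.
#' @param N_total per-year total abundances for the catch-effort component
#'   (required when `spec$catch_effort`).
#' @return Negative log joint likelihood (before integrating random effects).
#' @export
spr_joint_negloglik <- function(par, data, telemetry, spec, entry_abundance,
                                N_total = NULL) {
  Y <- length(data$years)
  delta <- if (is.null(par$delta)) numeric(Y) else par$delta
  nu <- if (is.null(par$nu)) numeric(Y) else par$nu
  s <- survival_prob(par$s_base, delta)
  P <- harvest_probability(par$c_base, data$effort, nu)
  eh <- expected_harvest(entry_abundance, P, P, s)
  x <- c(data$juvenile_harvest, data$adult_harvest)
  ev <- c(eh$expected[, "juvenile"], eh$expected[, "adult"])
  ll <- cohort_loglik(x, conditional_cell_probs(ev))
  ll <- ll + edge_cohort_loglik(data$adult_harvest[1L], entry_abundance[1L],
                                P[1L])
  ll <- ll + edge_cohort_loglik(data$juvenile_harvest[Y],
                                entry_abundance[Y + 1L], P[Y])
  year_map <- data.frame(
    year = rep(data$years, 3L),
    age_class = rep(c("pooled", "juvenile", "adult"), each = Y),
    prob = rep(P, 3L)
  )
  ll <- ll + telemetry_loglik(telemetry, year_map)
  if (isTRUE(spec$catch_effort)) {
    if (is.null(N_total)) stop("catch-effort component requires N_total")
    ll <- ll + catch_effort_loglik(
      data$juvenile_harvest + data$adult_harvest, N_total, P)
  }
  if (spec$effects == "RE") {
    ll <- ll + re_penalty(
      delta = if (spec$re_survival) delta,
      nu = if (spec$re_vulnerability) nu,
      sigma_s = par$sigma_s, sigma_c = par$sigma_c)
  }
  -ll
}
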