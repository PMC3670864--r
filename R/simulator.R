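# Stochastic two-age-class Leslie-matrix population simulator.
#
# Emulates the design of the Monte Carlo performance study: a population
# with a single survival probability and a single harvest vulnerability
# shared by both age classes, Poisson recruitment linear in the number of
# breeding adults, binomial harvest and binomial natural survival drawn
# separately per age class and year, and lognormal / logit-normal annual
# random variation shared across age classes within a year.

#' Configuration for the population simulator
#'
#' Defaults reproduce the base study conditions: survival 0.50, harvest rate
#' 0.40 at mean effort, fecundity `exp(2) ~ 7.39` young per adult with a
#' calibrated pre-recruitment survival factor so that the expected growth
#' rate is exactly 1, a stationary population of about 40,000 animals, 75
#' simulated years of which the final 25 are kept as the reconstruction
#' data, and a common standard deviation applied to the three demographic
#' processes (logit scale for survival, log scale for vulnerability and
#' fecundity).
#'
#' Stationarity calibration: with survival 0.5 and harvest 0.4 a stationary
#' two-class population requires `1 / ((1 - P) s) - 1 = 7/3` effective
#' recruits per adult, so the pre-recruitment factor is
#' `(7/3) / fecundity`.
#'
#' @param sigma common interannual standard deviation (0, 0.1, 0.2, 0.3 in
#'   the study design).
#' @param base_survival,base_harvest_rate,fecundity base demographic rates;
#'   the harvest rate applies at mean effort.
#' @param target_abundance approximate stationary total abundance.
#' @param years_total,years_keep simulated years and final years kept.
#' @param telemetry_years 1 (year 12 only) or 6 (years 9-14), 30 animals at
#'   risk per year.
#' @param scenario `"baseline"`, `"increasing_s"`, `"decreasing_s"` or
#'   `"periodic_recruitment"` (robustness scenarios; applied over the kept
#'   years on top of the stochastic draws).
#' @param effort_cv lognormal coefficient of variation of annual effort
#'   around its mean (effort units are scaled so mean effort is 1).
#' @param scenario_trend total logit-survival change across the kept years
#'   for the survival-trend scenarios.
#' @param scenario_pulse multiplicative recruitment pulse height (crash is
#'   its reciprocal) for the periodic-recruitment scenario.
#' @param seed integer seed; every simulated quantity derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sigma = 0, base_survival = 0.5,
                       base_harvest_rate = 0.4, fecundity = exp(2),
                       target_abundance = 40000, years_total = 75L,
                       years_keep = 25L, telemetry_years = 6L,
                       scenario = c("baseline", "increasing_s",
                                    "decreasing_s", "periodic_recruitment"),
                       effort_cv = 0.05, scenario_trend = 0.4,
                       scenario_pulse = 1.5, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(sigma >= 0, base_survival > 0, base_survival < 1,
            base_harvest_rate > 0, base_harvest_rate < 1, fecundity > 0,
            years_keep <= years_total, telemetry_years %in% c(1L, 6L))
  structure(
    list(sigma = sigma, base_survival = base_survival,
         base_harvest_rate = base_harvest_rate, fecundity = fecundity,
         target_abundance = target_abundance,
         years_total = as.integer(years_total),
         years_keep = as.integer(years_keep),
         telemetry_years = as.integer(telemetry_years), scenario = scenario,
         effort_cv = effort_cv, scenario_trend = scenario_trend,
         scenario_pulse = scenario_pulse, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Scenario modifiers on the per-year parameter trajectories
#'
#' Returns the deterministic additive logit-survival shifts and
#' multiplicative recruitment factors layered onto the stochastic draws of
#' the kept years: a linear survival trend for `increasing_s` /
#' `decreasing_s`, and for `periodic_recruitment` pulses (years 4, 8, 12,
#' ...) with reciprocal crashes in the alternating even years (2, 6, 10,
#' ...).  The baseline scenario is the identity.
#'
#' @param config a [sim_config()].
#' @return List with `survival_shift` and `recruit_mult`, each of length
#'   `years_keep`.
#' @export
apply_scenario <- function(config) {
  K <- config$years_keep
  shift <- numeric(K)
  mult <- rep(1, K)
  tr <- config$scenario_trend
  if (config$scenario == "increasing_s") {
    shift <- seq(-tr / 2, tr / 2, length.out = K)
  } else if (config$scenario == "decreasing_s") {
    shift <- seq(tr / 2, -tr / 2, length.out = K)
  } else if (config$scenario == "periodic_recruitment") {
    yr <- seq_len(K)
    mult[yr %% 4L == 0L] <- config$scenario_pulse
    mult[yr %% 4L == 2L] <- 1 / config$scenario_pulse
  }
  list(survival_shift = shift, recruit_mult = mult)
}

#' Simulate a harvested two-age-class population
#'
#' Evolves the population for `years_total` years from an initial stationary
#' age distribution and keeps the final `years_keep` years as age-at-harvest
#' data.  Each year, in order: binomial harvest per age class, binomial
#' survival of the non-harvested animals through the nonharvest season
#' (survivors of both classes pool into next year's adults), and Poisson
#' recruitment of next year's juveniles proportional to the resulting number
#' of breeding adults.  Harvest counts are treated as known.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_population`: list with `aah` (an
#'   [aah_data()] for the kept years, years labelled 1..K), `telemetry`
#'   ([simulate_telemetry()] output), `truth` (data frame of true juvenile,
#'   adult and total pre-harvest abundance per kept year), and `rates` (true
#'   per-year survival, harvest probability and recruitment rate).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  Tn <- config$years_total
  K <- config$years_keep
  first_keep <- Tn - K + 1L

  c_vuln <- -log(1 - config$base_harvest_rate)  # mean effort scaled to 1
  recruit_rate <- 1 / ((1 - config$base_harvest_rate) *
                         config$base_survival) - 1
  prerecruit_factor <- recruit_rate / config$fecundity

  scen <- apply_scenario(config)
  sdlog_f <- sqrt(log(1 + config$effort_cv^2))
  effort <- exp(stats::rnorm(Tn, -sdlog_f^2 / 2, sdlog_f))
  delta <- stats::rnorm(Tn, 0, config$sigma)
  nu <- stats::rnorm(Tn, 0, config$sigma)
  eps <- stats::rnorm(Tn, 0, config$sigma)

  shift <- numeric(Tn)
  mult <- rep(1, Tn)
  shift[first_keep:Tn] <- scen$survival_shift
  mult[first_keep:Tn] <- scen$recruit_mult

  A <- config$target_abundance / (1 + recruit_rate)
  J <- recruit_rate * A
  J <- round(J); A <- round(A)

  s_all <- stats::plogis(stats::qlogis(config$base_survival) + delta + shift)
  P_all <- -expm1(-c_vuln * effort * exp(nu))
  r_all <- config$fecundity * exp(eps) * mult * prerecruit_factor
  Jv <- Av <- hJv <- hAv <- integer(Tn)
  for (t in seq_len(Tn)) {
    hJ <- stats::rbinom(1L, J, P_all[t])
    hA <- stats::rbinom(1L, A, P_all[t])
    sJ <- stats::rbinom(1L, J - hJ, s_all[t])
    sA <- stats::rbinom(1L, A - hA, s_all[t])
    Jv[t] <- J; Av[t] <- A; hJv[t] <- hJ; hAv[t] <- hA
    A_next <- sJ + sA
    J_next <- stats::rpois(1L, r_all[t] * A_next)
    if (A_next + J_next == 0L) {
      stop("simulated population went extinct in year ", t,
           "; re-run with a different seed")
    }
    J <- J_next
    A <- A_next
  }
  out <- data.frame(year = seq_len(Tn), juvenile = Jv, adult = Av, hJ = hJv,
                    hA = hAv, effort = effort, s = s_all, P = P_all,
                    recruit = r_all)

  kept <- out[out$year >= first_keep, ]
  aah <- aah_data(years = seq_len(K), juvenile_harvest = kept$hJ,
                  adult_harvest = kept$hA, effort = kept$effort)
  pop <- structure(
    list(aah = aah,
         truth = data.frame(year = seq_len(K), juvenile = kept$juvenile,
                            adult = kept$adult,
                            total = kept$juvenile + kept$adult),
         rates = data.frame(year = seq_len(K), survival = kept$s,
                            harvest_prob = kept$P,
                            recruit_rate = kept$recruit),
         config = config),
    class = "sim_population"
  )
  pop$telemetry <- simulate_telemetry(pop, config$telemetry_years)
  pop
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated population:", nrow(x$truth), "kept years, total abundance ",
      round(min(x$truth$total)), "-", round(max(x$truth$total)), "\n")
  invisible(x)
}

#' Simulate radiotelemetry for a simulated population
#'
#' Thirty tagged animals at risk per telemetry year; the number harvested is
#' binomial with that year's true harvest probability.  Telemetry sits in
#' the middle of the kept series: year 12 for the single-year design, years
#' 9-14 for the six-year design (for kept series shorter than the 25-year
#' study design, the window is centred instead).
#'
#' @param pop a `sim_population`.
#' @param design 1 or 6 (telemetry years).
#' @param n_tagged animals at risk per year (30 in the study design).
#' @return A [telemetry_data()] with pooled age class.
#' @export
simulate_telemetry <- function(pop, design = 6L, n_tagged = 30L) {
  stopifnot(inherits(pop, "sim_population"), design %in% c(1L, 6L))
  K <- nrow(pop$truth)
  years <- if (K >= 14L) {
    if (design == 1L) 12L else 9:14
  } else {
    if (design == 1L) ceiling(K / 2) else {
      start <- max(1L, floor((K - 6L) / 2) + 1L)
      seq(start, length.out = min(6L, K))
    }
  }
  P <- pop$rates$harvest_prob[years]
  telemetry_data(year = years, age_class = rep("pooled", length(years)),
                 n_at_risk = rep(n_tagged, length(years)),
                 n_harvested = stats::rbinom(length(years), n_tagged, P))
}
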