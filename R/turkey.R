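# Two-season wild-turkey reconstruction with known removals.
#
# Event order within a year, fixed by the species' spring-centred life
# history: spring non-permittee removals -> spring permitted harvest ->
# juveniles graduate to the adult class -> summer survival (22 weeks) ->
# fall harvest (known removal) -> winter survival (24 weeks) -> next spring.
# The two survival intervals share a single annual rate, so summer x winter
# interval survival recomposes the annual probability exactly.

WEEKS_SUMMER <- 22
WEEKS_WINTER <- 24
WEEKS_YEAR <- WEEKS_SUMMER + WEEKS_WINTER
WEEKS_CALENDAR_YEAR <- 52

#' Age-class harvest probability for the turkey model
#'
#' Identical catch-effort form as [harvest_probability()] but evaluated with
#' an age-class-specific vulnerability coefficient (`c_J` for juveniles,
#' `c_A` for adults) and that class's annual random effect.
#'
#' @inheritParams harvest_probability
#' @return Harvest probability in `[0, 1)`.
#' @export
turkey_harvest_prob <- function(c, f, nu = 0) harvest_probability(c, f, nu)

#' Interval survival over a within-year period
#'
#' The annual survival probability (logit-shifted by the annual random
#' effect when present) raised to `weeks / 46`, the fraction of the
#' survival year the interval covers: 22 weeks between spring and fall
#' harvest (summer), 24 weeks between fall harvest and the next spring
#' (winter).  The summer and winter interval survivals multiply back to the
#' annual probability exactly.
#'
#' With the default `weeks_per_year = 46` (the two survival intervals) the
#' summer and winter interval survivals multiply back to the annual
#' probability exactly.  [fit_turkey()] instead scales by the 52-week
#' calendar year, under which the likelihood exposes `s^(46/52)` of annual
#' natural mortality (the harvest seasons themselves are excluded); see the
#' methods vignette for why that parameterization reconciles the fitted and
#' data-implied survival.
#'
#' @param s_base annual survival probability in (0, 1].
#' @param weeks 22 (summer) or 24 (winter).
#' @param delta logit-scale annual random effect (default 0).
#' @param weeks_per_year denominator of the scaling exponent: 46 (default,
#'   summer + winter) or 52 (calendar year).
#' @return Interval survival probability.
#' @examples
#' interval_survival(0.58, 22)  # ~0.771
#' @export
interval_survival <- function(s_base, weeks, delta = 0,
                              weeks_per_year = WEEKS_YEAR) {
  if (!all(weeks %in% c(WEEKS_SUMMER, WEEKS_WINTER))) {
    stop("weeks must be 22 (summer) or 24 (winter)")
  }
  if (!weeks_per_year %in% c(WEEKS_YEAR, WEEKS_CALENDAR_YEAR)) {
    stop("weeks_per_year must be 46 or 52")
  }
  if (any(s_base <= 0) || any(s_base > 1)) {
    stop("s_base must lie in (0, 1]")
  }
  s <- ifelse(s_base == 1, 1, stats::plogis(stats::qlogis(s_base) + delta))
  s^(weeks / weeks_per_year)
}

#' Expected adults available next spring
#'
#' Propagates both age classes through one year of the two-season process:
#' survivors of the spring permitted harvest (juveniles net of spring
#' non-permittee removals graduate to adults) survive the 22-week summer,
#' lose the fall adult harvest as a known removal, and survive the 24-week
#' winter.  Fall juvenile removals do not enter: they are confounded with
#' poult production, for which no estimate exists.
#'
#' @param J,A juvenile and adult abundance immediately before the spring
#'   non-permittee removals of year i.
#' @param R_spring_juvenile,R_spring_adult,R_fall_adult known removals of
#'   year i.
#' @param P_juvenile,P_adult spring permitted harvest probabilities of year
#'   i.
#' @param s annual survival probability of year i.
#' @param delta logit-scale survival random effect (default 0).
#' @param weeks_per_year exponent denominator passed to
#'   [interval_survival()] (46 by default; [fit_turkey()] uses 52).
#' @return Expected adult abundance just before the spring removals of year
#'   i + 1.
#' @export
expected_adults_next_year <- function(J, A, R_spring_juvenile,
                                      R_spring_adult, R_fall_adult,
                                      P_juvenile, P_adult, s, delta = 0,
                                      weeks_per_year = WEEKS_YEAR) {
  Javail <- J - R_spring_juvenile
  Aavail <- A - R_spring_adult
  if (Javail < 0) stop("juvenile abundance below spring removals")
  if (Aavail < 0) stop("adult abundance below spring removals")
  summer <- (Javail * (1 - P_juvenile) + Aavail * (1 - P_adult)) *
    interval_survival(s, WEEKS_SUMMER, delta, weeks_per_year)
  fall <- summer - R_fall_adult
  if (fall < 0) stop("adult abundance below fall removals")
  fall * interval_survival(s, WEEKS_WINTER, delta, weeks_per_year)
}

#' Spring total abundance series from a turkey fit
#'
#' The Horvitz-Thompson estimator per age class plus the known spring
#' non-permittee removals: `N_i = x_J/P_J + x_A/P_A + R_J + R_A`.  Interval
#' endpoints use the fit's delta-method + second-stage standard errors.
#' Because fall removals enter as known constants, abundance variability is
#' slightly understated.
#'
#' @param fit an `spr_fit` from [fit_turkey()].
#' @return Data frame `year`, `estimate`, `se`, `lcl`, `ucl` (same as
#'   `fit$abundance`).
#' @export
spring_abundance <- function(fit) {
  stopifnot(inherits(fit, "spr_fit"))
  fit$abundance
}

#' Fit the two-season turkey reconstruction model
#'
#' Horvitz-Thompson random-effects reconstruction with age-class-specific
#' harvest vulnerabilities (`two_c = TRUE`) or a single shared coefficient,
#' a single annual natural survival parameter scaled to the 22-week summer
#' and 24-week winter intervals, annual vulnerability random effects per age
#' class (and optionally a survival random effect), known removals, and the
#' 1996-2000 radiotelemetry auxiliary likelihood.  The marginal likelihood
#' is maximized with the Laplace approximation, alternating with
#' Horvitz-Thompson plug-in updates of the class availabilities.
#'
#' @param data,telemetry,removals as returned by [turkey_data()].
#' @param re character subset of `c("cJ", "cA", "s")` naming the processes
#'   carrying annual random effects (default: both vulnerabilities, no
#'   survival effect — the selected model).
#' @param two_c use separate juvenile/adult vulnerability coefficients?
#' @param init optional overrides of starting values (`s_base`,
#'   `harvest_rate`, `sigma`).
#' @param control as in [fit_spr()].
#' @return An `spr_fit` whose `par` table carries `c_juvenile`, `c_adult`,
#'   `s_annual`, the active `sigma_*`, and the harvest probabilities at mean
#'   effort (`P_juvenile_mean`, `P_adult_mean`); `abundance` is the spring
#'   total series including removals.
#' @export
fit_turkey <- function(data, telemetry, removals, re = c("cJ", "cA"),
                       two_c = TRUE, init = NULL, control = list()) {
  stopifnot(inherits(data, "aah_data"), inherits(telemetry, "telemetry_data"),
            inherits(removals, "removal_data"))
  if (!all(re %in% c("cJ", "cA", "s"))) stop("unknown random-effect name")
  ctl <- fit_control(control)
  Y <- length(data$years)
  xJ <- as.numeric(data$juvenile_harvest)
  xA <- as.numeric(data$adult_harvest)
  f <- data$effort

  rem <- removals[match(data$years, removals$year), ]
  if (anyNA(rem$spring_npr_juvenile)) {
    stop("removals must cover every reconstruction year")
  }

  ini <- list(s_base = 0.5, harvest_rate = 0.3, sigma = 0.1)
  ini[names(init)] <- init
  c0 <- -log(1 - ini$harvest_rate) / mean(f)
  PJ0 <- harvest_probability(c0, f)
  PA0 <- PJ0

  tel_j <- telemetry[telemetry$age_class == "juvenile", ]
  tel_a <- telemetry[telemetry$age_class == "adult", ]
  tel_years <- sort(unique(telemetry$year))
  if (!identical(sort(tel_j$year), tel_years) ||
      !identical(sort(tel_a$year), tel_years)) {
    stop("turkey telemetry needs a juvenile and an adult record per year")
  }
  tel_idx <- match(tel_years, data$years)
  if (anyNA(tel_idx)) stop("telemetry year outside the study years")
  tel_j <- tel_j[match(tel_years, tel_j$year), ]
  tel_a <- tel_a[match(tel_years, tel_a$year), ]

  use_cJ <- "cJ" %in% re
  use_cA <- "cA" %in% re
  use_s <- "s" %in% re

  tmb_data <- list(
    model_code = 2L, xJ = xJ, xA = xA, f = f,
    RA_fall = as.numeric(rem$fall_harvest_adult),
    telt_year = as.integer(tel_idx),
    telt_mJ = as.numeric(tel_j$n_at_risk),
    telt_yJ = as.numeric(tel_j$n_harvested),
    telt_mA = as.numeric(tel_a$n_at_risk),
    telt_yA = as.numeric(tel_a$n_harvested),
    re_cJ = as.integer(use_cJ), re_cA = as.integer(use_cA),
    re_s = as.integer(use_s),
    w_summer = WEEKS_SUMMER / WEEKS_CALENDAR_YEAR,
    w_winter = WEEKS_WINTER / WEEKS_CALENDAR_YEAR,
    f_mean = mean(f)
  )
  tmb_par <- list(
    log_cv = c(log(c0), log(c0)), logit_s = stats::qlogis(ini$s_base),
    log_sig = rep(log(ini$sigma), 3L),
    nu2 = numeric(2L * Y), dlt = numeric(Y)
  )
  map <- list()
  if (!two_c) map$log_cv <- factor(c(1L, 1L))
  sig_map <- seq_len(3L)
  sig_map[!c(use_cJ, use_cA, use_s)] <- NA
  if (anyNA(sig_map)) map$log_sig <- factor(sig_map)
  nu_map <- seq_len(2L * Y)
  if (!use_cJ) nu_map[seq_len(Y)] <- NA
  if (!use_cA) nu_map[Y + seq_len(Y)] <- NA
  if (!two_c && use_cJ && use_cA) {
    # single shared vulnerability: one shared effect per year
    nu_map[Y + seq_len(Y)] <- nu_map[seq_len(Y)]
    sig_map2 <- c(1L, 1L, if (use_s) 2L else NA)
    map$log_sig <- factor(sig_map2)
  }
  if (anyNA(nu_map) || !two_c) map$nu2 <- factor(nu_map)
  if (!use_s) map$dlt <- factor(rep(NA, Y))
  random <- c(if (use_cJ || use_cA) "nu2", if (use_s) "dlt")

  obj <- TMB::MakeADFun(data = tmb_data, parameters = tmb_par, map = map,
                        random = random, DLL = "sprgame", silent = !ctl$trace)
  bounds <- spr_bounds(names(obj$par), ctl)

  # The class availabilities are Horvitz-Thompson functions of the current
  # parameters inside the likelihood, so one maximization suffices.
  opt <- stats::nlminb(obj$par, obj$fn, obj$gr, lower = bounds$lower,
                       upper = bounds$upper,
                       control = list(iter.max = ctl$iter_max,
                                      eval.max = 2L * ctl$iter_max))
  n_outer <- 1L
  outer_converged <- TRUE

  sdr <- spr_sdreport(obj, opt, tmb_data, tmb_par, map, random, bounds, ctl)
  pl <- obj$env$parList()
  PJ <- harvest_probability(exp(pl$log_cv[1L]), f, pl$nu2[seq_len(Y)])
  PA <- harvest_probability(exp(pl$log_cv[2L]), f, pl$nu2[Y + seq_len(Y)])

  rep_tab <- sdr$report
  est_N <- rep_tab[rep_tab$name == "Nht", "estimate"]
  se_N <- rep_tab[rep_tab$name == "Nht", "se"]
  v2 <- xJ * (1 - PJ) / PJ^2 + xA * (1 - PA) / PA^2
  se_N <- sqrt(se_N^2 + v2)
  removals_spring <- rem$spring_npr_juvenile + rem$spring_npr_adult
  est_N <- est_N + removals_spring
  abundance <- data.frame(year = data$years, estimate = est_N, se = se_N,
                          lcl = est_N - 1.96 * se_N,
                          ucl = est_N + 1.96 * se_N)
  juv_ab <- rep_tab[rep_tab$name == "NhtJ", "estimate"] +
    rem$spring_npr_juvenile

  par_tab <- turkey_par_table(sdr$sdr, use_cJ, use_cA, use_s, two_c)

  eb <- rbind(
    if (use_cJ) data.frame(name = "nu_juvenile", year = data$years,
                           estimate = pl$nu2[seq_len(Y)]),
    if (use_cA) data.frame(name = "nu_adult", year = data$years,
                           estimate = pl$nu2[Y + seq_len(Y)]),
    if (use_s) data.frame(name = "delta", year = data$years,
                          estimate = pl$dlt)
  )

  k <- length(opt$par)
  structure(
    list(model = list(family = "turkey_HT_RE", re = re, two_c = two_c),
         code = "turkey_HT_RE", par = par_tab, opt = opt,
         sdreport = sdr$sdr, eb_effects = eb, abundance = abundance,
         juvenile_abundance = data.frame(year = data$years,
                                         estimate = juv_ab),
         loglik = -opt$objective, aic = 2 * opt$objective + 2 * k, df = k,
         fitted_harvest_prob = data.frame(year = data$years, juvenile = PJ,
                                          adult = PA),
         fitted_survival = stats::plogis(pl$logit_s),
         converged = (opt$convergence == 0L) && outer_converged,
         n_outer_iterations = n_outer, years = data$years),
    class = "spr_fit"
  )
}

turkey_par_table <- function(sdr, use_cJ, use_cA, use_s, two_c) {
  if (is.null(sdr)) {
    return(data.frame(name = character(), estimate = numeric(),
                      se = numeric()))
  }
  fx <- summary_fixed(sdr)
  sm <- TMB::summary.sdreport(sdr, select = "report")
  rp <- data.frame(name = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                   row.names = NULL)
  rows <- list()
  cv <- fx[fx$name == "log_cv", ]
  if (nrow(cv) == 1L) cv <- rbind(cv, cv)
  rows$cJ <- data.frame(name = "c_juvenile", estimate = exp(cv$estimate[1L]),
                        se = cv$se[1L] * exp(cv$estimate[1L]))
  rows$cA <- data.frame(name = "c_adult", estimate = exp(cv$estimate[2L]),
                        se = cv$se[2L] * exp(cv$estimate[2L]))
  for (nm in c("s_annual", "P_juv_mean", "P_adult_mean")) {
    r <- rp[rp$name == nm, ]
    lab <- c(s_annual = "s_annual", P_juv_mean = "P_juvenile_mean",
             P_adult_mean = "P_adult_mean")[[nm]]
    if (nrow(r)) {
      rows[[nm]] <- data.frame(name = lab, estimate = r$estimate[1L],
                               se = r$se[1L])
    }
  }
  sig <- fx[fx$name == "log_sig", ]
  lab <- c("sigma_c_juvenile", "sigma_c_adult", "sigma_s")[
    c(use_cJ, use_cA, use_s)]
  if (nrow(sig) && nrow(sig) == length(lab)) {
    rows$sig <- data.frame(name = lab, estimate = exp(sig$estimate),
                           se = sig$se * exp(sig$estimate))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Mixture chi-square p-value for a variance component on the boundary
#'
#' Likelihood-ratio test of `sigma^2 = 0` against `sigma^2 > 0`: the null
#' reference is the 50:50 mixture of a point mass at zero and chi-square
#' with 1 df, so `p = 0.5 P(chi2_1 > stat)` for `stat > 0` and `p = 1` at
#' `stat = 0`.
#'
#' @param stat likelihood-ratio statistic (non-negative).
#' @return p-value.
#' @examples
#' mixture_chisq_pvalue(2.706)  # 0.05
#' @export
mixture_chisq_pvalue <- function(stat) {
  if (any(stat < 0)) stop("LRT statistic must be non-negative")
  ifelse(stat == 0, 1, 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Model selection for the turkey reconstruction
#'
#' Fits the candidate fixed-effect structures (single versus age-specific
#' vulnerability coefficients) and ranks them by AIC, then tests each
#' variance component of the best fixed-effect structure on its boundary by
#' likelihood-ratio tests against the 50:50 mixture chi-square reference.
#' Candidates that fail to converge are excluded with a note.
#'
#' @param data,telemetry,removals as returned by [turkey_data()].
#' @param control passed to [fit_turkey()].
#' @return List with `aic` (ranked data frame over fixed-effect
#'   structures), `lrt` (variance-component tests), `selected` (the
#'   selected `spr_fit`), and `fits` (all fitted candidates).
#' @export
turkey_model_selection <- function(data, telemetry, removals,
                                   control = list()) {
  cand <- list(
    two_c = list(two_c = TRUE, re = c("cJ", "cA")),
    one_c = list(two_c = FALSE, re = c("cJ", "cA"))
  )
  fits <- lapply(cand, function(cd) {
    tryCatch(fit_turkey(data, telemetry, removals, re = cd$re,
                        two_c = cd$two_c, control = control),
             error = function(e) NULL)
  })
  ok <- vapply(fits, function(ft) !is.null(ft) && ft$converged, logical(1))
  note <- if (all(ok)) NULL else paste("excluded unconverged candidate(s):",
                                       paste(names(cand)[!ok],
                                             collapse = ", "))
  aic <- data.frame(
    structure = names(cand)[ok],
    df = vapply(fits[ok], `[[`, numeric(1), "df"),
    loglik = vapply(fits[ok], `[[`, numeric(1), "loglik"),
    aic = vapply(fits[ok], `[[`, numeric(1), "aic"))
  aic <- aic[order(aic$aic), ]
  best <- aic$structure[1L]
  two_c <- cand[[best]]$two_c

  # variance-component tests on the selected fixed-effect structure
  full <- fit_turkey(data, telemetry, removals, re = c("cJ", "cA", "s"),
                     two_c = two_c, control = control)
  drop_tests <- list(
    sigma_s = c("cJ", "cA"),
    sigma_c_adult = c("cJ", "s"),
    sigma_c_juvenile = c("cA", "s")
  )
  lrt <- do.call(rbind, lapply(names(drop_tests), function(nm) {
    red <- tryCatch(fit_turkey(data, telemetry, removals,
                               re = drop_tests[[nm]], two_c = two_c,
                               control = control),
                    error = function(e) NULL)
    if (is.null(red)) {
      return(data.frame(component = nm, stat = NA_real_, p = NA_real_))
    }
    stat <- max(0, 2 * (full$loglik - red$loglik))
    data.frame(component = nm, stat = stat, p = mixture_chisq_pvalue(stat))
  }))

  selected_re <- c("cJ", "cA", if (lrt$p[lrt$component == "sigma_s"] < 0.05)
    "s")
  selected <- if (setequal(selected_re, c("cJ", "cA", "s"))) full else
    fits[[best]]
  list(aic = aic, lrt = lrt, selected = selected, fits = fits, note = note)
}

#' Correlation of juvenile spring abundance with the lagged poult-hen index
#'
#' Pearson correlation between the estimated spring juvenile abundance of
#' year i and the poult-to-hen ratio observed in year i - 1 (the poults
#' counted in early summer are the following spring's one-year-old
#' juveniles).
#'
#' @param fit an `spr_fit` from [fit_turkey()].
#' @param removals the [removal_data()] carrying `poult_hen_ratio`,
#'   including the year before reconstruction starts.
#' @return Pearson correlation, or `NA` with a warning when either series
#'   is constant.
#' @export
poult_hen_comparison <- function(fit, removals) {
  stopifnot(inherits(fit, "spr_fit"))
  juv <- fit$juvenile_abundance
  if (is.null(juv)) stop("fit carries no juvenile abundance series")
  lag_years <- juv$year - 1L
  idx <- match(lag_years, removals$year)
  if (anyNA(idx)) {
    stop("poult-hen ratio missing for year ", lag_years[which(is.na(idx))[1L]])
  }
  ratio <- removals$poult_hen_ratio[idx]
  if (anyNA(ratio)) stop("poult-hen ratio missing within the lagged window")
  if (stats::sd(ratio) == 0 || stats::sd(juv$estimate) == 0) {
    warning("constant series: correlation undefined")
    return(NA_real_)
  }
  stats::cor(juv$estimate, ratio)
}
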