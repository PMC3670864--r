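# Fitting machinery for the small-game reconstruction models.
#
# The marginal likelihood (random effects integrated out by the Laplace
# approximation) is maximized with a bounded quasi-Newton optimizer on
# transformed scales (logit survival, log vulnerability, log sigma).  For
# the Horvitz-Thompson families the cohort entry abundances are HT estimates
# evaluated at the current parameter values inside the likelihood itself;
# only the catch-effort auxiliary holds its annual abundances fixed as data,
# updated in an EM-style outer loop until the total abundance stabilizes.

fit_control <- function(control = list()) {
  out <- list(outer_tol = 1e-6, max_outer = 100L, sigma_lower = 1e-3,
              sigma_upper = 3, iter_max = 2000L, trace = FALSE)
  out[names(control)] <- control
  out
}

#' Fit a statistical population reconstruction model
#'
#' Maximum (marginal) likelihood fit of the two-age-class age-at-harvest
#' model selected by `spec`, returning parameter estimates with
#' inverse-Hessian standard errors, empirical Bayes random-effect
#' predictions, and the annual total-abundance series with delta-method plus
#' second-stage Horvitz-Thompson uncertainty.
#'
#' Starting values follow a fixed convention (base survival 0.5, harvest rate
#' 0.3 at mean effort, random-effect standard deviations 0.1, cohort
#' abundances harvest/0.3) and can be overridden through `init`.  The fit is
#' deterministic: fitting the same data twice gives identical results.
#'
#' @param data an [aah_data()] object.
#' @param telemetry a [telemetry_data()] object, or `NULL` for none.
#' @param spec an [model_spec()]; default `HT_RE` without catch-effort.
#' @param init optional list overriding `s_base`, `harvest_rate` (at mean
#'   effort) and `sigma` starting values.
#' @param control list of optimizer settings: `outer_tol` (relative change
#'   in total abundance ending the HT loop, default 1e-6), `max_outer`
#'   (default 100), `sigma_lower`/`sigma_upper` bounds for random-effect
#'   standard deviations, `iter_max` inner iterations.
#' @return An object of class `spr_fit`; see [print.spr_fit()].
#' @export
fit_spr <- function(data, telemetry = NULL, spec = model_spec("HT", "RE"),
                    init = NULL, control = list()) {
  stopifnot(inherits(data, "aah_data"), inherits(spec, "spr_model_spec"))
  if (is.null(telemetry)) telemetry <- telemetry_data()
  ctl <- fit_control(control)
  Y <- length(data$years)
  xJ <- as.numeric(data$juvenile_harvest)
  xA <- as.numeric(data$adult_harvest)
  f <- data$effort

  ini <- list(s_base = 0.5, harvest_rate = 0.3, sigma = 0.1)
  ini[names(init)] <- init
  c0 <- -log(1 - ini$harvest_rate) / mean(f)
  P0 <- harvest_probability(c0, f)
  entryN0 <- pmax(c(xA[1L] / P0[1L], xJ / P0), 1e-8)
  Ntot0 <- pmax((xJ + xA) / P0, xJ + xA)

  tel_idx <- match(telemetry$year, data$years)
  if (anyNA(tel_idx)) {
    stop("telemetry year ", telemetry$year[which(is.na(tel_idx))[1L]],
         " outside the study years")
  }

  aa <- spec$abundance == "AA"
  use_d <- spec$effects == "RE" && spec$re_survival
  use_n <- spec$effects == "RE" && spec$re_vulnerability

  tmb_data <- list(
    model_code = 1L, xJ = xJ, xA = xA, f = f,
    tel_year = as.integer(tel_idx), tel_m = as.numeric(telemetry$n_at_risk),
    tel_y = as.numeric(telemetry$n_harvested),
    Ntot = round(Ntot0),
    aa_mode = as.integer(aa), use_ce = as.integer(spec$catch_effort),
    re_s = as.integer(use_d), re_c = as.integer(use_n)
  )
  tmb_par <- list(
    logit_s = stats::qlogis(ini$s_base), log_c = log(c0),
    log_sigma_s = log(ini$sigma), log_sigma_c = log(ini$sigma),
    delta = numeric(Y), nu = numeric(Y),
    logN = log(entryN0)
  )
  map <- list()
  if (!use_d) map$delta <- factor(rep(NA, Y))
  if (!use_n) map$nu <- factor(rep(NA, Y))
  if (!use_d) map$log_sigma_s <- factor(NA)
  if (!use_n) map$log_sigma_c <- factor(NA)
  if (!aa) map$logN <- factor(rep(NA, Y + 1L))
  random <- c(if (use_d) "delta", if (use_n) "nu")

  obj <- TMB::MakeADFun(data = tmb_data, parameters = tmb_par, map = map,
                        random = random, DLL = "sprgame", silent = !ctl$trace)
  bounds <- spr_bounds(names(obj$par), ctl,
                       logN_lower = log(c(xA[1L], xJ) + 0.5))

  # The HT entry abundances are functions of the current parameters inside
  # the likelihood, so a single maximization suffices; only the catch-effort
  # auxiliary treats its annual abundances as plug-in data, updated in an
  # EM-style outer loop until the total abundance series stabilizes.
  em_loop <- !aa && spec$catch_effort
  par_cur <- obj$par
  tot_old <- sum(Ntot0)
  n_outer <- 0L
  outer_converged <- !em_loop
  opt <- NULL
  repeat {
    n_outer <- n_outer + 1L
    opt <- stats::nlminb(par_cur, obj$fn, obj$gr, lower = bounds$lower,
                         upper = bounds$upper,
                         control = list(iter.max = ctl$iter_max,
                                        eval.max = 2L * ctl$iter_max))
    par_cur <- opt$par
    if (!em_loop) break
    pl <- obj$env$parList()
    P_hat <- harvest_probability(exp(pl$log_c), f, pl$nu)
    tot_new <- sum((xJ + xA) / P_hat)
    rel <- abs(tot_new - tot_old) / max(tot_old, 1)
    tot_old <- tot_new
    obj$env$data$Ntot <- round(pmax((xJ + xA) / P_hat, xJ + xA))
    if (rel < ctl$outer_tol) {
      outer_converged <- TRUE
      break
    }
    if (n_outer >= ctl$max_outer) break
  }
  # final pass so the reported optimum matches the final plug-in abundances
  if (em_loop) {
    opt <- stats::nlminb(par_cur, obj$fn, obj$gr, lower = bounds$lower,
                         upper = bounds$upper,
                         control = list(iter.max = ctl$iter_max,
                                        eval.max = 2L * ctl$iter_max))
  }

  sdr <- spr_sdreport(obj, opt, tmb_data, tmb_par, map, random, bounds, ctl)
  pl <- obj$env$parList()

  P_hat <- harvest_probability(exp(pl$log_c), f, pl$nu)
  s_hat <- survival_prob(stats::plogis(pl$logit_s), pl$delta)

  fixed <- summary_fixed(sdr$sdr)
  par_tab <- natural_par_table(fixed, use_d, use_n, aa)

  rep_tab <- sdr$report  # ADREPORT: Nann estimate + se
  est_N <- rep_tab[rep_tab$name == "Nann", "estimate"]
  se_N <- rep_tab[rep_tab$name == "Nann", "se"]
  if (!aa) {
    v2 <- vapply(seq_len(Y), function(i) {
      ht_second_stage_var(c(xJ[i], xA[i]), c(P_hat[i], P_hat[i]))
    }, numeric(1))
    se_N <- sqrt(se_N^2 + v2)
  }
  abundance <- data.frame(year = data$years, estimate = est_N, se = se_N,
                          lcl = est_N - 1.96 * se_N,
                          ucl = est_N + 1.96 * se_N)

  eb <- NULL
  if (use_d) {
    eb <- data.frame(name = "delta", year = data$years, estimate = pl$delta)
  }
  if (use_n) {
    eb <- rbind(eb, data.frame(name = "nu", year = data$years,
                               estimate = pl$nu))
  }

  k <- length(opt$par)
  structure(
    list(model = spec, code = model_code(spec), par = par_tab,
         opt = opt, sdreport = sdr$sdr, eb_effects = eb,
         abundance = abundance, loglik = -opt$objective,
         aic = 2 * opt$objective + 2 * k, df = k,
         fitted_survival = s_hat, fitted_harvest_prob = P_hat,
         converged = (opt$convergence == 0L) && outer_converged,
         n_outer_iterations = n_outer,
         years = data$years),
    class = "spr_fit"
  )
}

# Box constraints on the transformed outer parameter vector, by name.
spr_bounds <- function(par_names, ctl, logN_lower = NULL) {
  lower <- rep(-Inf, length(par_names))
  upper <- rep(Inf, length(par_names))
  lower[par_names == "logit_s"] <- -7; upper[par_names == "logit_s"] <- 7
  for (nm in c("log_c", "log_cv")) {
    lower[par_names == nm] <- -20; upper[par_names == nm] <- 5
  }
  for (nm in c("log_sigma_s", "log_sigma_c", "log_sig")) {
    lower[par_names == nm] <- log(ctl$sigma_lower)
    upper[par_names == nm] <- log(ctl$sigma_upper)
  }
  if (any(par_names == "logN")) {
    lower[par_names == "logN"] <- logN_lower
    upper[par_names == "logN"] <- log(1e9)
  }
  list(lower = lower, upper = upper)
}

# sdreport with a fallback: variance components stuck at their boundary can
# leave the marginal Hessian singular, in which case they are profiled out
# (fixed at the boundary) and the remaining parameters re-reported.
spr_sdreport <- function(obj, opt, tmb_data, tmb_par, map, random, bounds,
                         ctl) {
  sdr <- try(suppressWarnings(TMB::sdreport(obj, par.fixed = opt$par)),
             silent = TRUE)
  rep_tab <- sdreport_table(sdr)
  bad <- inherits(sdr, "try-error") || anyNA(rep_tab$se)
  if (bad) {
    at_lb <- names(opt$par) %in% c("log_sigma_s", "log_sigma_c", "log_sig") &
      opt$par < log(ctl$sigma_lower) + 1e-6
    if (any(at_lb)) {
      pl <- obj$env$parList()
      frozen <- unique(names(opt$par)[at_lb])
      for (nm in frozen) {
        map[[nm]] <- factor(rep(NA, length(tmb_par[[nm]])))
      }
      for (nm in names(pl)) tmb_par[[nm]] <- pl[[nm]]
      obj2 <- TMB::MakeADFun(data = tmb_data, parameters = tmb_par,
                             map = map, random = random, DLL = "sprgame",
                             silent = TRUE)
      keep <- !(names(opt$par) %in% frozen)
      opt2 <- stats::nlminb(opt$par[keep], obj2$fn, obj2$gr,
                            lower = bounds$lower[keep],
                            upper = bounds$upper[keep],
                            control = list(iter.max = ctl$iter_max))
      sdr2 <- try(suppressWarnings(TMB::sdreport(obj2, par.fixed = opt2$par)),
                  silent = TRUE)
      rep2 <- sdreport_table(sdr2)
      if (!inherits(sdr2, "try-error") && !anyNA(rep2$se)) {
        return(list(sdr = sdr2, report = rep2))
      }
    }
    if (inherits(sdr, "try-error")) {
      warning("standard-error computation failed; SEs reported as missing")
      return(list(sdr = NULL, report = rep_tab))
    }
    warning("non-positive-definite Hessian; some SEs reported as missing")
  }
  list(sdr = sdr, report = rep_tab)
}

sdreport_table <- function(sdr) {
  if (inherits(sdr, "try-error") || is.null(sdr)) {
    return(data.frame(name = character(), estimate = numeric(),
                      se = numeric()))
  }
  sm <- TMB::summary.sdreport(sdr, select = "report")
  data.frame(name = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
             row.names = NULL)
}

summary_fixed <- function(sdr) {
  if (is.null(sdr)) return(NULL)
  sm <- TMB::summary.sdreport(sdr, select = "fixed")
  data.frame(name = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
             row.names = NULL)
}

# Back-transform the fixed-parameter table to the natural scale.
natural_par_table <- function(fixed, use_d, use_n, aa) {
  if (is.null(fixed)) {
    return(data.frame(name = character(), estimate = numeric(),
                      se = numeric()))
  }
  rows <- list()
  grab <- function(nm) fixed[fixed$name == nm, , drop = FALSE]
  r <- grab("logit_s")
  if (nrow(r)) {
    s <- stats::plogis(r$estimate)
    rows$s_base <- data.frame(name = "s_base", estimate = s,
                              se = r$se * s * (1 - s))
  }
  r <- grab("log_c")
  if (nrow(r)) {
    rows$c_base <- data.frame(name = "c_base", estimate = exp(r$estimate),
                              se = r$se * exp(r$estimate))
  }
  if (use_d) {
    r <- grab("log_sigma_s")
    if (nrow(r)) {
      rows$sigma_s <- data.frame(name = "sigma_s",
                                 estimate = exp(r$estimate),
                                 se = r$se * exp(r$estimate))
    }
  }
  if (use_n) {
    r <- grab("log_sigma_c")
    if (nrow(r)) {
      rows$sigma_c <- data.frame(name = "sigma_c",
                                 estimate = exp(r$estimate),
                                 se = r$se * exp(r$estimate))
    }
  }
  if (aa) {
    r <- grab("logN")
    if (nrow(r)) {
      rows$N0 <- data.frame(
        name = paste0("N", seq_len(nrow(r))),
        estimate = exp(r$estimate), se = r$se * exp(r$estimate))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Parameter estimates and standard errors of a fit
#' @param fit an `spr_fit` object.
#' @return Data frame with columns `name`, `estimate`, `se` (natural scale).
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "spr_fit"))
  fit$par
}

#' @export
print.spr_fit <- function(x, ...) {
  cat("Statistical population reconstruction fit: model ", x$code,
      if (!is.null(x$model$catch_effort) && x$model$catch_effort)
        " (+ catch-effort)", "\n", sep = "")
  cat("  marginal log-likelihood: ", format(x$loglik, digits = 6),
      "   AIC: ", format(x$aic, digits = 6),
      "   converged: ", x$converged, "\n", sep = "")
  cat("  outer (HT/EM) iterations: ", x$n_outer_iterations, "\n", sep = "")
  cat("Parameters:\n")
  print(x$par, digits = 4)
  ab <- x$abundance
  cat("Total annual abundance: ", format(round(ab$estimate[1L])), " (",
      ab$year[1L], ") ... ", format(round(ab$estimate[nrow(ab)])), " (",
      ab$year[nrow(ab)], ")\n", sep = "")
  invisible(x)
}
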