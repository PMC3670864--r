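# Fitting machinery: recovery, determinism, model-family agreement and
# uncertainty behaviour.  One zero-variation and one low-variation
# population are shared across tests.

pop0 <- simulate_population(sim_config(sigma = 0, telemetry_years = 6L,
                                       seed = 1405))

test_that("HT_RE recovers the generating parameters on zero-variation data", {
  fit <- suppressWarnings(fit_spr(pop0$aah, pop0$telemetry,
                                  model_spec("HT", "RE")))
  expect_true(fit$converged)
  par <- fit$par
  s_hat <- par$estimate[par$name == "s_base"]
  s_se <- par$se[par$name == "s_base"]
  expect_lt(abs(s_hat - 0.5), 2 * s_se + 0.02)
  c_hat <- par$estimate[par$name == "c_base"]
  c_se <- par$se[par$name == "c_base"]
  P_hat <- harvest_probability(c_hat, mean(pop0$aah$effort))
  P_lo <- harvest_probability(max(c_hat - 2 * c_se, 1e-8),
                              mean(pop0$aah$effort))
  P_hi <- harvest_probability(c_hat + 2 * c_se, mean(pop0$aah$effort))
  expect_lt(abs(P_hat - 0.40), (P_hi - P_lo) / 2 + 0.02)
  # intervals bracket their estimates
  expect_true(all(fit$abundance$lcl <= fit$abundance$estimate))
  expect_true(all(fit$abundance$ucl >= fit$abundance$estimate))
})

test_that("fitting the same data twice is bit-for-bit identical", {
  f1 <- suppressWarnings(fit_spr(pop0$aah, pop0$telemetry,
                                 model_spec("HT", "RE")))
  f2 <- suppressWarnings(fit_spr(pop0$aah, pop0$telemetry,
                                 model_spec("HT", "RE")))
  expect_identical(f1$opt$par, f2$opt$par)
  expect_identical(f1$abundance, f2$abundance)
})

test_that("HT_FE and HT_RE overlap when no interannual variation is present", {
  re <- suppressWarnings(fit_spr(pop0$aah, pop0$telemetry,
                                 model_spec("HT", "RE")))
  fe <- suppressWarnings(fit_spr(pop0$aah, pop0$telemetry,
                                 model_spec("HT", "FE")))
  expect_true(fe$converged)
  rel <- abs(fe$abundance$estimate - re$abundance$estimate) /
    re$abundance$estimate
  expect_lt(mean(rel), 0.05)
})

test_that("the AA family agrees with HT on expectation-exact data", {
  # counts generated exactly at the recursion's expected values
  d <- make_exact_aah(Y = 8L, N_entry = 30000, P = 0.4, s = 0.5)
  tel <- telemetry_data(year = 4, age_class = "pooled", n_at_risk = 3000,
                        n_harvested = 1200)
  aa <- suppressWarnings(fit_spr(d, tel,
                                 model_spec("AA", "FE", catch_effort = TRUE)))
  ht <- suppressWarnings(fit_spr(d, tel, model_spec("HT", "FE")))
  rel <- abs(aa$abundance$estimate - ht$abundance$estimate) /
    ht$abundance$estimate
  expect_lt(mean(rel), 0.05)
})

test_that("inverse-Hessian SEs match closed-form binomial information", {
  # pure binomial toy: nll(p) for y successes of n, information n/(p(1-p))
  n <- 200; y <- 64
  nll <- function(p) -dbinom(y, n, p, log = TRUE)
  p_hat <- y / n
  H <- sprgame:::fd_hessian(function(p) nll(p[1L]), p_hat)
  se_fd <- sqrt(1 / H[1L, 1L])
  se_exact <- sqrt(p_hat * (1 - p_hat) / n)
  expect_equal(se_fd, se_exact, tolerance = 1e-4)
})

test_that("information scales with count size: 4x counts halve relative SE", {
  d1 <- make_exact_aah(Y = 6L, N_entry = 10000)
  d4 <- make_exact_aah(Y = 6L, N_entry = 40000)
  tel1 <- telemetry_data(3, "pooled", 250, 100)
  tel4 <- telemetry_data(3, "pooled", 1000, 400)
  f1 <- suppressWarnings(fit_spr(d1, tel1, model_spec("HT", "FE")))
  f4 <- suppressWarnings(fit_spr(d4, tel4, model_spec("HT", "FE")))
  r1 <- f1$par$se[f1$par$name == "c_base"] /
    f1$par$estimate[f1$par$name == "c_base"]
  r4 <- f4$par$se[f4$par$name == "c_base"] /
    f4$par$estimate[f4$par$name == "c_base"]
  expect_equal(r4 / r1, 0.5, tolerance = 0.15)
})

test_that("marginal likelihood ignores telemetry record order", {
  pop <- simulate_population(sim_config(sigma = 0.1, telemetry_years = 6L,
                                        seed = 77))
  tel <- pop$telemetry
  tel_rev <- tel[rev(seq_len(nrow(tel))), ]
  f1 <- suppressWarnings(fit_spr(pop$aah, tel, model_spec("HT", "RE")))
  f2 <- suppressWarnings(fit_spr(pop$aah, tel_rev, model_spec("HT", "RE")))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$par$estimate, f2$par$estimate, tolerance = 1e-6)
})
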