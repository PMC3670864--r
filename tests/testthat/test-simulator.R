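test_that("the simulator is reproducible given a seed", {
  cfg <- sim_config(sigma = 0.2, seed = 17)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$aah, p2$aah)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$telemetry, p2$telemetry)
})

test_that("counting conservation holds along each realization", {
  pop <- simulate_population(sim_config(sigma = 0.3, seed = 4))
  tr <- pop$truth
  hJ <- pop$aah$juvenile_harvest
  hA <- pop$aah$adult_harvest
  expect_true(all(hJ <= tr$juvenile))
  expect_true(all(hA <= tr$adult))
  K <- nrow(tr)
  # next year's adults are survivors of this year's post-harvest animals
  expect_true(all(tr$adult[-1L] <=
                    (tr$juvenile - hJ + tr$adult - hA)[-K]))
})

test_that("the calibrated base population is stationary near 40,000", {
  # with effort held constant only demographic noise remains, isolating the
  # recruitment calibration
  pop <- simulate_population(sim_config(sigma = 0, effort_cv = 0, seed = 21))
  expect_true(all(abs(pop$truth$total - 40000) / 40000 < 0.2))
  # the default effort jitter turns total abundance into a slow random walk;
  # the population still hovers around the target on average
  pop2 <- simulate_population(sim_config(sigma = 0, seed = 21))
  expect_true(mean(pop2$truth$total) > 20000 &&
                mean(pop2$truth$total) < 80000)
})

test_that("the expected-value projection has unit growth rate", {
  r <- 1 / ((1 - 0.4) * 0.5) - 1
  start <- c(juvenile = 28000, adult = 12000)
  end <- project_expected(start["juvenile"], start["adult"], P = 0.4,
                          s = 0.5, r = r, years = 1000)
  expect_lt(abs(end["juvenile"] / start["juvenile"] - 1), 0.01)
  expect_lt(abs(end["adult"] / start["adult"] - 1), 0.01)
})

test_that("long-run rate variation reproduces the design's 2 sd bands", {
  # pool realized rates over many independent study-length runs
  collect_rates <- function(sigma, n_runs = 50L) {
    out <- lapply(seq_len(n_runs), function(k) {
      # high-variation runs occasionally go extinct; skip those seeds
      tryCatch(simulate_population(sim_config(sigma = sigma,
                                              seed = 8000 + k))$rates,
               error = function(e) NULL)
    })
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  }
  prf <- (1 / (0.6 * 0.5) - 1) / exp(2)  # pre-recruitment factor

  r1 <- collect_rates(0.1)
  qs <- quantile(r1$survival, c(0.025, 0.975))
  expect_equal(as.numeric(qs), c(0.450, 0.550), tolerance = 0.02)
  qf <- quantile(r1$recruit_rate / prf, c(0.025, 0.975))
  expect_equal(as.numeric(qf), c(6.050, 9.025), tolerance = 0.03)

  r3 <- collect_rates(0.3)
  qs3 <- quantile(r3$survival, c(0.025, 0.975))
  expect_equal(as.numeric(qs3), c(0.354, 0.646), tolerance = 0.03)
  qf3 <- quantile(r3$recruit_rate / prf, c(0.025, 0.975))
  expect_equal(as.numeric(qf3), c(4.055, 13.464), tolerance = 0.05)
  # logit-survival is centred on the base rate
  expect_equal(mean(qlogis(r3$survival)), 0, tolerance = 0.03)
})

test_that("robustness scenarios modify the kept-year trajectories as designed", {
  base <- apply_scenario(sim_config(scenario = "baseline"))
  expect_true(all(base$survival_shift == 0) && all(base$recruit_mult == 1))

  inc <- simulate_population(sim_config(sigma = 0.1,
                                        scenario = "increasing_s", seed = 9))
  s <- inc$rates$survival
  expect_gt(mean(s[21:25]), mean(s[1:5]))
  dec <- simulate_population(sim_config(sigma = 0.1,
                                        scenario = "decreasing_s", seed = 9))
  expect_lt(mean(dec$rates$survival[21:25]), mean(dec$rates$survival[1:5]))

  per <- apply_scenario(sim_config(scenario = "periodic_recruitment"))
  yr <- seq_len(25)
  expect_true(all(per$recruit_mult[yr %% 4 == 0] > 1))
  expect_true(all(per$recruit_mult[yr %% 4 == 2] < 1))
  expect_true(all(per$recruit_mult[yr %% 2 == 1] == 1))
})

test_that("telemetry designs place records in the study's middle years", {
  pop <- simulate_population(sim_config(seed = 2, telemetry_years = 1L))
  expect_identical(pop$telemetry$year, 12L)
  expect_identical(pop$telemetry$n_at_risk, 30L)
  tel6 <- simulate_telemetry(pop, 6L)
  expect_identical(tel6$year, 9:14)
  expect_identical(nrow(tel6), 6L)
})
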