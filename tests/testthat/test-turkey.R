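# Two-season turkey model.  The full-data fit is computed once and shared.

tk <- turkey_data()
turkey_fit <- fit_turkey(tk$aah, tk$telemetry, tk$removals)

test_that("interval survival scales by week fraction and recomposes exactly", {
  expect_equal(interval_survival(0.58, 22), 0.58^(22 / 46))
  expect_equal(interval_survival(0.58, 22), 0.771, tolerance = 1e-3)
  expect_identical(interval_survival(1, 24), 1)
  s <- 0.63
  expect_equal(interval_survival(s, 22) * interval_survival(s, 24), s)
  # calendar-year scaling exposes 46/52 of annual mortality
  expect_equal(interval_survival(s, 22, weeks_per_year = 52) *
                 interval_survival(s, 24, weeks_per_year = 52),
               s^(46 / 52))
  expect_error(interval_survival(0.5, 30), "22.*24")
})

test_that("the adult chain propagates removals and harvests in order", {
  # lossless closed population: everyone graduates
  expect_equal(expected_adults_next_year(1000, 2000, 0, 0, 0, 0, 0, 1), 3000)
  # exhaustion: all juveniles removed, all adults harvested
  expect_equal(expected_adults_next_year(1000, 2000, 1000, 0, 0, 0.11, 1, 0.6),
               0)
  # hand-computed chain
  J <- 1000; A <- 2000
  sS <- 0.58^(22 / 46); sW <- 0.58^(24 / 46)
  hand <- ((((J - 50) * (1 - 0.11) + 2000 * (1 - 0.40)) * sS) - 200) * sW
  expect_equal(
    expected_adults_next_year(J, A, 50, 0, 200, 0.11, 0.40, 0.58), hand)
  expect_error(expected_adults_next_year(100, 200, 150, 0, 0, 0.1, 0.4, 0.5),
               "below spring removals")
  expect_error(expected_adults_next_year(10, 20, 0, 0, 500, 0.1, 0.4, 0.5),
               "below fall removals")
})

test_that("the boundary mixture chi-square test matches its closed form", {
  expect_identical(mixture_chisq_pvalue(0), 1)
  expect_equal(mixture_chisq_pvalue(2.706), 0.05, tolerance = 1e-3)
  # oracle: mixture CDF 0.5 + 0.5 * pchisq
  for (stat in c(0.5, 1.3, 4.2)) {
    expect_equal(mixture_chisq_pvalue(stat),
                 1 - (0.5 + 0.5 * pchisq(stat, 1)))
  }
  expect_error(mixture_chisq_pvalue(-1), "non-negative")
})

test_that("the reconstruction fit is converged, reproducible and coherent", {
  expect_true(turkey_fit$converged)
  f2 <- fit_turkey(tk$aah, tk$telemetry, tk$removals)
  expect_identical(turkey_fit$opt$par, f2$opt$par)
  # abundance dominates the observable removals and harvest every year
  rem <- tk$removals[match(tk$aah$years, tk$removals$year), ]
  floor_n <- tk$aah$juvenile_harvest + tk$aah$adult_harvest +
    rem$spring_npr_juvenile + rem$spring_npr_adult
  expect_true(all(turkey_fit$abundance$estimate >= floor_n))
  expect_true(all(turkey_fit$abundance$lcl <= turkey_fit$abundance$estimate))
  # spring_abundance is the fit's abundance series
  expect_identical(spring_abundance(turkey_fit), turkey_fit$abundance)
})

test_that("juvenile abundance tracks the lagged productivity index", {
  r <- poult_hen_comparison(turkey_fit, tk$removals)
  expect_gt(r, 0.6)
  # identical (rescaled) series correlate perfectly
  fake <- turkey_fit
  ratio <- tk$removals$poult_hen_ratio[match(tk$aah$years - 1L,
                                             tk$removals$year)]
  fake$juvenile_abundance <- data.frame(year = tk$aah$years,
                                        estimate = 100 + 500 * ratio)
  expect_equal(poult_hen_comparison(fake, tk$removals), 1)
  # constant index: correlation undefined
  const <- tk$removals
  const$poult_hen_ratio <- 2
  expect_warning(out <- poult_hen_comparison(fake, const), "constant")
  expect_true(is.na(out))
})

test_that("model selection prefers class-specific vulnerabilities", {
  sel <- turkey_model_selection(tk$aah, tk$telemetry, tk$removals)
  expect_identical(sel$aic$structure[1L], "two_c")
  expect_true(all(diff(sel$aic$aic) >= 0))
  lrt <- sel$lrt
  expect_true(all(lrt$p >= 0 & lrt$p <= 1, na.rm = TRUE))
  # survival variance is not supported; class vulnerability variances are
  expect_gt(lrt$p[lrt$component == "sigma_s"], 0.05)
  expect_identical(sort(sel$selected$model$re), c("cA", "cJ"))
})

test_that("a fitted reconstruction writes and its parameters survive", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_fit(turkey_fit, path)
  out <- utils::read.csv(path)
  expect_true(all(c("parameter", "abundance", "random_effect") %in%
                    out$component))
  ab <- out[out$component == "abundance", ]
  expect_equal(ab$estimate, turkey_fit$abundance$estimate, tolerance = 1e-6)
})
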