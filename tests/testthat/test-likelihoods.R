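test_that("conditional cell probabilities normalize expected counts", {
  expect_equal(conditional_cell_probs(c(120, 120)), c(0.5, 0.5))
  # hand normalization of the 1000 * {0.4, 0.12, 0.036} chain
  expect_equal(conditional_cell_probs(c(400, 120, 36)),
               c(400, 120, 36) / 556)
  expect_equal(conditional_cell_probs(c(400, 120, 36)),
               c(0.7194, 0.2158, 0.0647), tolerance = 1e-3)
  expect_identical(conditional_cell_probs(5), 1)
  expect_error(conditional_cell_probs(c(0, 0)), "degenerate")
  set.seed(11)
  for (rep in 1:20) {
    p <- conditional_cell_probs(runif(sample(2:6, 1L), 0, 10))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("cohort likelihood matches small-case enumeration", {
  # two animals, two cells at p = 1/2: 2 * 0.25
  expect_equal(cohort_loglik(c(1, 1), c(0.5, 0.5)), log(0.5))
  expect_equal(cohort_loglik(c(2, 0), c(0.5, 0.5)), log(0.25))
  # single-cell cohort is deterministic given harvest
  expect_identical(cohort_loglik(7, 1), 0)
  expect_warning(out <- cohort_loglik(c(1, 1), c(1, 0)), "zero probability")
  expect_lt(out, -1e9)
})

test_that("cohort likelihood equals the sequential conditional-binomial product", {
  set.seed(23)
  for (rep in 1:25) {
    k <- sample(2:4, 1L)
    p <- conditional_cell_probs(runif(k, 0.2, 3))
    x <- as.numeric(stats::rmultinom(1L, sample(5:40, 1L), p))
    expect_equal(cohort_loglik(x, p), sequential_binomial_loglik(x, p),
                 tolerance = 1e-10)
  }
})

test_that("edge cohort component is a plain binomial", {
  expect_equal(edge_cohort_loglik(3, 10, 0.3), dbinom(3, 10, 0.3, log = TRUE))
  # continuous sizes go through the gamma form
  expect_equal(edge_cohort_loglik(0, 12.5, 0.2), 12.5 * log(0.8))
  expect_warning(out <- edge_cohort_loglik(5, 3, 0.5), "impossible")
  expect_lt(out, -1e9)
})

test_that("telemetry likelihood is a binomial sum over records", {
  tel <- telemetry_data(year = 12, age_class = "pooled", n_at_risk = 30,
                        n_harvested = 12)
  P <- data.frame(year = 12, age_class = "pooled", prob = 0.4)
  expect_equal(telemetry_loglik(tel, P),
               lchoose(30, 12) + 12 * log(0.4) + 18 * log(0.6))
  # zero at risk contributes nothing
  tel0 <- telemetry_data(12, "pooled", 0, 0)
  expect_identical(telemetry_loglik(tel0, P), 0)
  # impossible record under P = 0
  telbad <- telemetry_data(12, "pooled", 30, 3)
  P0 <- data.frame(year = 12, age_class = "pooled", prob = 0)
  expect_warning(out <- telemetry_loglik(telbad, P0), "impossible")
  expect_lt(out, -1e9)
  expect_error(telemetry_loglik(tel, P0[0, ]), "no harvest probability")
})

test_that("catch-effort component treats harvest as binomial from abundance", {
  expect_equal(catch_effort_loglik(40, 100, 0.4),
               dbinom(40, 100, 0.4, log = TRUE))
  expect_identical(catch_effort_loglik(25, 25, 1), 0)
  expect_equal(catch_effort_loglik(0, 80, 0.3), 80 * log(0.7))
  expect_warning(out <- catch_effort_loglik(50, 40, 0.5), "below")
  expect_lt(out, -1e9)
})

test_that("random-effects penalty matches the normal density", {
  Y <- 7L
  expect_equal(re_penalty(delta = numeric(Y), nu = numeric(Y), sigma_s = 1,
                          sigma_c = 1),
               2 * Y * log(1 / sqrt(2 * pi)))
  expect_equal(re_penalty(delta = 0.3, sigma_s = 0.3),
               dnorm(0.3, 0, 0.3, log = TRUE))
  expect_identical(re_penalty(), 0)  # fixed-effects model
  expect_error(re_penalty(delta = c(0, 0), sigma_s = 0), "positive")
})

test_that("removing telemetry changes the joint by exactly its term", {
  d <- make_exact_aah()
  tel <- telemetry_data(year = 3, age_class = "pooled", n_at_risk = 30,
                        n_harvested = 12)
  spec <- model_spec("HT", "FE")
  par <- list(s_base = 0.5, c_base = -log(0.6), sigma_s = NULL,
              sigma_c = NULL)
  P <- harvest_probability(par$c_base, d$effort)
  entry <- c(d$adult_harvest[1L] / P[1L], d$juvenile_harvest / P)
  with_tel <- spr_joint_negloglik(par, d, tel, spec, entry)
  without <- spr_joint_negloglik(par, d, telemetry_data(), spec, entry)
  tel_term <- telemetry_loglik(tel, data.frame(year = 3,
                                               age_class = "pooled",
                                               prob = P[3L]))
  expect_equal(with_tel - without, -tel_term, tolerance = 1e-10)
})

test_that("the multinomial peaks when counts sit at expected proportions", {
  p <- conditional_cell_probs(c(400, 120, 36, 10))
  x0 <- 3000 * p
  base <- cohort_loglik(x0, p)
  for (eps in c(-25, -10, 10, 25)) {
    x <- x0 + c(eps, -eps, 0, 0)
    expect_lt(cohort_loglik(x, p), base)
    x <- x0 + c(0, eps, 0, -eps)
    expect_lt(cohort_loglik(x, p), base)
  }
})
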