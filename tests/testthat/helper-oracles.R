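# Independent oracles used across the test files.

# Multinomial log-likelihood as the product of sequential conditional
# binomials: cell i against everything after it.  Independent of
# cohort_loglik's lgamma form.
sequential_binomial_loglik <- function(x, p) {
  ll <- 0
  rem_n <- sum(x)
  rem_p <- 1
  for (i in seq_len(length(x) - 1L)) {
    ll <- ll + dbinom(x[i], rem_n, p[i] / rem_p, log = TRUE)
    rem_n <- rem_n - x[i]
    rem_p <- rem_p - p[i]
  }
  ll
}

# Exact marginal negative log-likelihood of the conjugate problem
# y_k ~ N(u, sd_y), u ~ N(0, sd_u): y is jointly normal with covariance
# sd_y^2 I + sd_u^2 J.
gaussian_marginal_nll <- function(y, sd_y, sd_u) {
  n <- length(y)
  Sigma <- diag(sd_y^2, n) + sd_u^2
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  0.5 * (n * log(2 * pi) + as.numeric(ld) +
           drop(y %*% solve(Sigma, y)))
}

# Deterministic expected-value projection of the two-class model (no
# stochasticity): one year of harvest, survival, and recruitment.
project_expected <- function(J, A, P, s, r, years) {
  J <- unname(J)
  A <- unname(A)
  for (i in seq_len(years)) {
    A_next <- (J * (1 - P) + A * (1 - P)) * s
    J <- r * A_next
    A <- A_next
  }
  c(juvenile = J, adult = A)
}

# A small deterministic age-at-harvest dataset whose counts equal the
# rounded expected values of the cohort recursion at known parameters.
make_exact_aah <- function(Y = 6L, N_entry = 20000, P = 0.4, s = 0.5) {
  eh <- expected_harvest(rep(N_entry, Y + 1L), rep(P, Y), rep(P, Y),
                         rep(s, Y))
  aah_data(years = seq_len(Y),
           juvenile_harvest = round(eh$expected[, "juvenile"]),
           adult_harvest = round(eh$expected[, "adult"]),
           effort = rep(1, Y))
}
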