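# Generic Laplace approximation to a marginal negative log-likelihood.
#
# Reference machinery mirroring what the compiled fitting path does with
# automatic differentiation: the random effects are profiled to their
# conditional mode by Newton iteration with finite-difference derivatives,
# and the Gaussian integral correction uses the Hessian at that mode.

# Central finite-difference gradient.
fd_gradient <- function(fn, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- xm <- x
    xp[i] <- x[i] + hi
    xm[i] <- x[i] - hi
    g[i] <- (fn(xp) - fn(xm)) / (2 * hi)
  }
  g
}

# Central finite-difference Hessian (symmetric).
fd_hessian <- function(fn, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  hv <- h * pmax(1, abs(x))
  f0 <- fn(x)
  for (i in seq_len(n)) {
    xp <- xm <- x
    xp[i] <- x[i] + hv[i]
    xm[i] <- x[i] - hv[i]
    H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / hv[i]^2
    if (i < n) {
      for (j in seq(i + 1L, n)) {
        xpp <- xpm <- xmp <- xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + hv[c(i, j)]
        xmm[c(i, j)] <- x[c(i, j)] - hv[c(i, j)]
        xpm[i] <- x[i] + hv[i]; xpm[j] <- x[j] - hv[j]
        xmp[i] <- x[i] - hv[i]; xmp[j] <- x[j] + hv[j]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * hv[i] * hv[j])
      }
    }
  }
  H
}

#' Laplace-approximated marginal negative log-likelihood
#'
#' Approximates `-log ∫ exp(-nll(u)) du` where `nll` is a joint negative
#' log-likelihood as a function of the random-effect vector `u` (fixed
#' parameters held inside the closure).  The inner mode is located by Newton
#' iteration (finite-difference gradient and Hessian, Levenberg damping on
#' non-descent steps), and the approximation is
#' `nll(u_hat) - n/2 log(2*pi) + 1/2 log det H(u_hat)`.
#'
#' With an empty random-effect vector the joint value itself is returned.
#' The approximation is exact whenever `nll` is quadratic in `u`
#' (linear-Gaussian inner problems).
#'
#' @param nll function of the random-effect vector returning the joint
#'   negative log-likelihood.
#' @param u_init starting values for the random effects (possibly length 0).
#' @param tol convergence tolerance on the inner gradient norm.
#' @param max_iter maximum Newton iterations.
#' @return A list with `value` (marginal negative log-likelihood), `mode`
#'   (inner optimum), `hessian`, and `converged`.  When the inner
#'   optimization fails, `value` is a large sentinel and
#'   `converged = FALSE`.
#' @examples
#' # one Gaussian random intercept, conjugate normal problem
#' nll <- function(u) -dnorm(1.3, u, 1, log = TRUE) - dnorm(u, 0, 2, log = TRUE)
#' laplace_marginal(nll, 0)$value  # equals -dnorm(1.3, 0, sqrt(5), log=TRUE)
#' @export
laplace_marginal <- function(nll, u_init, tol = 1e-8, max_iter = 50L) {
  n <- length(u_init)
  if (n == 0L) {
    return(list(value = nll(numeric(0)), mode = numeric(0),
                hessian = matrix(0, 0, 0), converged = TRUE))
  }
  u <- as.numeric(u_init)
  f <- nll(u)
  converged <- FALSE
  lambda <- 0
  for (it in seq_len(max_iter)) {
    g <- fd_gradient(nll, u)
    if (sqrt(sum(g^2)) < tol) {
      converged <- TRUE
      break
    }
    H <- fd_hessian(nll, u)
    step <- NULL
    lambda <- 0
    for (try in 1:12) {
      Hd <- H + diag(lambda, n)
      step <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (!is.null(step)) {
        fnew <- nll(u - step)
        if (is.finite(fnew) && fnew <= f + 1e-12) break
        step <- NULL
      }
      lambda <- if (lambda == 0) 1e-4 * max(abs(diag(H)), 1) else 10 * lambda
    }
    if (is.null(step)) break
    u <- u - step
    f <- nll(u)
  }
  if (!converged) {
    g <- fd_gradient(nll, u)
    converged <- sqrt(sum(g^2)) < max(tol, 1e-5)
  }
  H <- fd_hessian(nll, u)
  ld <- determinant(H, logarithm = TRUE)
  if (!converged || ld$sign <= 0) {
    warning("inner random-effects optimization did not converge to a ",
            "proper mode; returning sentinel marginal value")
    return(list(value = -NEG_INF_SENTINEL, mode = u, hessian = H,
                converged = FALSE))
  }
  list(value = f - n / 2 * log(2 * pi) + 0.5 * as.numeric(ld$modulus),
       mode = u, hessian = H, converged = TRUE)
}

#' Marginal negative log-likelihood of the small-game model (reference path)
#'
#' Wraps [spr_joint_negloglik()] in [laplace_marginal()] over whichever
#' random-effect vectors the model specification activates.  Slow
#' (finite-difference) but independent of the compiled path, and used to
#' validate it.
#'
#' @inheritParams spr_joint_negloglik
#' @param par fixed parameters only (`s_base`, `c_base`, `sigma_s`,
#'   `sigma_c`); random effects are integrated out.
#' @param entry_abundance per-cohort entry abundances, or `NULL` (the
#'   default for HT models) to use the Horvitz-Thompson estimates at the
#'   current parameter and random-effect values.
#' @param u_init optional warm start for the stacked random-effect vector.
#' @return As [laplace_marginal()].
#' @export
spr_marginal_negloglik <- function(par, data, telemetry, spec,
                                   entry_abundance = NULL, N_total = NULL,
                                   u_init = NULL) {
  Y <- length(data$years)
  use_d <- spec$effects == "RE" && spec$re_survival
  use_n <- spec$effects == "RE" && spec$re_vulnerability
  n_re <- Y * (use_d + use_n)
  if (is.null(u_init)) u_init <- numeric(n_re)
  nll <- function(u) {
    p <- par
    k <- 0
    p$delta <- if (use_d) u[seq_len(Y)] else numeric(Y)
    if (use_d) k <- Y
    p$nu <- if (use_n) u[k + seq_len(Y)] else numeric(Y)
    entry <- entry_abundance
    if (is.null(entry)) {
      P <- harvest_probability(p$c_base, data$effort, p$nu)
      entry <- c(data$adult_harvest[1L] / P[1L],
                 data$juvenile_harvest / P)
    }
    spr_joint_negloglik(p, data, telemetry, spec, entry, N_total)
  }
  laplace_marginal(nll, u_init)
}
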