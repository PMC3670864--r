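#' Horvitz-Thompson abundance for one harvest cell
#'
#' `N_hat = x / P`: the observed harvest count scaled up by the estimated
#' probability of harvest, under the binomial sampling assumption.
#'
#' @param x observed harvest count(s).
#' @param P harvest probability estimate(s) in (0, 1].
#' @return Abundance estimate(s); vectorized.
#' @examples
#' ht_cell_abundance(100, 0.4)  # 250
#' @export
ht_cell_abundance <- function(x, P) {
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(P < 0) || any(P > 1)) stop("P must lie in [0, 1]")
  out <- numeric(length(x))
  zero <- P == 0
  if (any(zero & x > 0)) {
    stop("zero harvest probability with a positive harvest count")
  }
  if (any(zero)) {
    warning("P = 0 with x = 0: abundance reported as 0")
  }
  out[!zero] <- x[!zero] / P[!zero]
  out
}

#' Second-stage sampling variance of a Horvitz-Thompson annual estimate
#'
#' The binomial component of the variance of `sum_a x_{ia} / P_{ia}`,
#' `sum_a x_{ia} (1 - P_{ia}) / P_{ia}^2`, added to the delta-method
#' parameter-uncertainty component to form the total abundance variance.
#'
#' @param x vector of cell counts contributing to the annual estimate.
#' @param P matching harvest probabilities.
#' @return Variance contribution (0 when all `P = 1`).
#' @export
ht_second_stage_var <- function(x, P) {
  if (any(P <= 0) || any(P > 1)) stop("P must lie in (0, 1]")
  sum(x * (1 - P) / P^2)
}

#' Pooled annual harvest probability across age classes
#'
#' Harvest-weighted pooling of per-class harvest probabilities, used for the
#' catch-effort auxiliary likelihood when classes differ in vulnerability.
#'
#' @param x_juvenile,x_adult per-year class harvest counts.
#' @param p_juvenile,p_adult per-year class harvest probabilities.
#' @return Per-year pooled probability (simple mean where no harvest).
#' @export
pooled_harvest_probability <- function(x_juvenile, x_adult, p_juvenile,
                                       p_adult) {
  tot <- x_juvenile + x_adult
  out <- (p_juvenile + p_adult) / 2
  pos <- tot > 0
  out[pos] <- (x_juvenile[pos] * p_juvenile[pos] +
                 x_adult[pos] * p_adult[pos]) / tot[pos]
  out
}

#' Total annual abundance from a fitted reconstruction
#'
#' For Horvitz-Thompson models, the sum of the per-cell estimators
#' `x_{i,J}/P_{i,J} + x_{i,A}/P_{i,A}`; for absolute-abundance models, the
#' model-propagated pre-harvest total.  This is the point-estimate column of
#' `fit$abundance`.
#'
#' @param fit an `spr_fit` object.
#' @return Data frame with columns `year` and `estimate`.
#' @export
total_annual_abundance <- function(fit) {
  stopifnot(inherits(fit, "spr_fit"))
  fit$abundance[, c("year", "estimate")]
}
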