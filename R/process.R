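#' Annual harvest probability under the catch-effort model
#'
#' The probability that an animal alive at the start of the harvest season of
#' a year is harvested, `P = 1 - exp(-c * f * exp(nu))`, where `c` is the
#' harvest vulnerability coefficient, `f` the hunter effort and `nu` a
#' temporal (log-scale, multiplicative on `c`) random effect.
#'
#' @param c positive harvest vulnerability coefficient.
#' @param f non-negative hunter effort.
#' @param nu random-effect value(s), default 0.
#' @return Harvest probability in `[0, 1)`; vectorized over `f` and `nu`.
#' @examples
#' harvest_probability(-log(0.6), 1)       # 0.40 at unit effort
#' harvest_probability(0.07246, 7.05)      # ~0.40 at the turkey mean effort
#' @export
harvest_probability <- function(c, f, nu = 0) {
  if (any(!is.finite(c)) || any(c <= 0)) {
    stop("vulnerability coefficient c must be positive")
  }
  if (any(f < 0)) stop("effort must be non-negative")
  -expm1(-c * f * exp(nu))
}

#' Annual natural survival probability with a logit-scale random effect
#'
#' `S = plogis(qlogis(s_base) + delta)`: the base survival probability is
#' shifted on the logit scale by the temporal random effect `delta`, keeping
#' the result in (0, 1).
#'
#' @param s_base base survival probability, strictly inside (0, 1).
#' @param delta random-effect value(s), default 0.
#' @return Survival probability in (0, 1); vectorized over `delta`.
#' @examples
#' survival_prob(0.5, c(-0.2, 0, 0.2))  # 0.450, 0.500, 0.550
#' @export
survival_prob <- function(s_base, delta = 0) {
  if (any(!is.finite(s_base)) || any(s_base <= 0) || any(s_base >= 1)) {
    stop("s_base must lie strictly inside (0, 1)")
  }
  stats::plogis(stats::qlogis(s_base) + delta)
}

#' Cohort layout of a two-age-class age-at-harvest matrix
#'
#' With only young-of-the-year and pooled-adult classes distinguishable, a
#' study of Y years involves Y + 1 cohorts, numbered chronologically: cohort
#' 1 is the pooled adult class already alive when the study starts (it
#' occupies the adult cell of every year), cohort j (2 <= j <= Y) enters as
#' the juvenile cell of year j - 1 and occupies the adult cells of years
#' j..Y, and cohort Y + 1 is the final year's juvenile cell alone.  Every
#' cell of the Y x 2 matrix belongs to the layout; adult cells are shared by
#' all cohorts alive in that year (the pooled composite).
#'
#' @param Y number of study years, at least 2.
#' @return An object of class `cohort_layout`: a list of Y + 1 data frames
#'   with columns `year` (1..Y) and `class` (`"juvenile"`/`"adult"`), one per
#'   cohort in chronological order.
#' @export
build_cohort_layout <- function(Y) {
  if (!is.numeric(Y) || length(Y) != 1L || Y < 2 || Y != round(Y)) {
    stop("Y must be a single integer >= 2")
  }
  Y <- as.integer(Y)
  cohorts <- vector("list", Y + 1L)
  cohorts[[1L]] <- data.frame(year = seq_len(Y), class = "adult")
  for (j in seq(2L, Y)) {
    e <- j - 1L
    cohorts[[j]] <- data.frame(
      year = seq(e, Y),
      class = c("juvenile", rep("adult", Y - e))
    )
  }
  cohorts[[Y + 1L]] <- data.frame(year = Y, class = "juvenile")
  structure(cohorts, Y = Y, class = "cohort_layout")
}

#' @export
print.cohort_layout <- function(x, ...) {
  cat("Cohort layout:", length(x), "cohorts over", attr(x, "Y"), "years\n")
  invisible(x)
}

#' Expected harvest counts from the cohort recursion
#'
#' Given per-cohort entry abundances, per-year harvest probabilities and
#' survival probabilities, propagates each cohort down its diagonal: the
#' expected harvest at the entry cell is `N_j * P(entry year)`; animals not
#' harvested survive the nonharvest season with probability `s_i` and are
#' exposed again the following year.  Expected counts in the pooled adult
#' cells accumulate additively over all cohorts present.
#'
#' @param entry_abundance numeric vector of length Y + 1: abundance of each
#'   cohort when it enters the matrix (cohort 1 = initial pooled adults).
#' @param p_juvenile,p_adult per-year harvest probabilities (length Y).  Pass
#'   the same vector twice when vulnerability is shared across age classes.
#' @param s per-year survival probabilities for the nonharvest season
#'   following each harvest (length Y; the final value is unused).
#' @param layout optionally a precomputed [build_cohort_layout()] result.
#' @return A list with `expected`, the Y x 2 matrix of pooled expected counts
#'   (columns `juvenile`, `adult`), and `cohorts`, a list giving each
#'   cohort's own expected counts along its cells.
#' @export
expected_harvest <- function(entry_abundance, p_juvenile, p_adult, s,
                             layout = NULL) {
  Y <- length(p_juvenile)
  stopifnot(length(p_adult) == Y, length(s) == Y,
            length(entry_abundance) == Y + 1L)
  if (any(entry_abundance < 0)) stop("entry abundances must be >= 0")
  if (is.null(layout)) layout <- build_cohort_layout(Y)
  EJ <- numeric(Y)
  EA <- numeric(Y)
  per_cohort <- vector("list", Y + 1L)
  for (j in seq_len(Y + 1L)) {
    cells <- layout[[j]]
    alive <- entry_abundance[j]
    e <- numeric(nrow(cells))
    for (k in seq_len(nrow(cells))) {
      i <- cells$year[k]
      P <- if (cells$class[k] == "juvenile") p_juvenile[i] else p_adult[i]
      e[k] <- alive * P
      if (cells$class[k] == "juvenile") EJ[i] <- EJ[i] + e[k]
      else EA[i] <- EA[i] + e[k]
      alive <- alive * (1 - P) * s[i]
    }
    per_cohort[[j]] <- e
  }
  list(expected = cbind(juvenile = EJ, adult = EA), cohorts = per_cohort)
}
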