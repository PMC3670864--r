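#' Age-at-harvest data for a two-age-class population
#'
#' Container for the primary SPR data: annual harvest counts of
#' young-of-the-year (juveniles) and of the pooled adult class, together with
#' an annual measure of hunter effort.  Years must be contiguous calendar
#' years; internally rows are indexed 1..Y in year order.
#'
#' @param years integer vector of calendar years, strictly increasing and
#'   contiguous, length Y >= 3.
#' @param juvenile_harvest,adult_harvest non-negative integer harvest counts,
#'   one per year.
#' @param effort positive hunter-effort values, one per year.  Units are
#'   arbitrary but must be consistent across years; harvest probability is
#'   modelled as `1 - exp(-c * effort)`.
#' @param effort_se optional standard errors of the effort estimates.  Carried
#'   as metadata only: effort is treated as known in all likelihoods.
#' @return An object of class `aah_data`: a list with elements `years`,
#'   `juvenile_harvest`, `adult_harvest`, `effort`, `effort_se`.
#' @seealso [read_age_at_harvest()], [fit_spr()]
#' @export
aah_data <- function(years, juvenile_harvest, adult_harvest, effort,
                     effort_se = NULL) {
  years <- as.integer(years)
  Y <- length(years)
  if (Y < 3) {
    stop("age-at-harvest data needs at least 3 years, got ", Y)
  }
  if (any(diff(years) != 1L)) {
    bad <- which(diff(years) != 1L)[1L]
    stop("years must be contiguous and increasing; break after row ", bad,
         " (year ", years[bad], ")")
  }
  check_counts <- function(x, what) {
    if (length(x) != Y) {
      stop(what, " must have one value per year (", Y, "), got ", length(x))
    }
    if (anyNA(x)) stop("missing value in ", what)
    if (any(x < 0)) {
      stop("negative count in ", what, " at row ", which(x < 0)[1L],
           " (year ", years[which(x < 0)[1L]], ")")
    }
    if (any(x != round(x))) {
      stop("non-integer count in ", what, " at row ", which(x != round(x))[1L])
    }
    as.integer(round(x))
  }
  juvenile_harvest <- check_counts(juvenile_harvest, "juvenile_harvest")
  adult_harvest <- check_counts(adult_harvest, "adult_harvest")
  effort <- as.numeric(effort)
  if (length(effort) != Y) stop("effort must have one value per year")
  if (anyNA(effort) || any(effort <= 0)) {
    stop("effort must be positive for every year; offending row ",
         which(!is.finite(effort) | effort <= 0)[1L])
  }
  if (!is.null(effort_se)) {
    effort_se <- as.numeric(effort_se)
    if (length(effort_se) != Y) stop("effort_se must have one value per year")
  }
  structure(
    list(years = years, juvenile_harvest = juvenile_harvest,
         adult_harvest = adult_harvest, effort = effort,
         effort_se = effort_se),
    class = "aah_data"
  )
}

#' @export
print.aah_data <- function(x, ...) {
  Y <- length(x$years)
  cat("Age-at-harvest data: ", Y, " years (", x$years[1L], "-", x$years[Y],
      ")\n", sep = "")
  cat("  juvenile harvest: ", sum(x$juvenile_harvest),
      " total;  adult harvest: ", sum(x$adult_harvest), " total\n", sep = "")
  cat("  mean effort: ", signif(mean(x$effort), 5), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.aah_data <- function(x, ...) {
  d <- data.frame(year = x$years, juvenile_harvest = x$juvenile_harvest,
                  adult_harvest = x$adult_harvest, effort = x$effort)
  if (!is.null(x$effort_se)) d$effort_se <- x$effort_se
  d
}

#' Radiotelemetry (tagging) data
#'
#' Records of tagged animals at risk of harvest and the number of them
#' harvested, by year and age class.  The number harvested is treated as a
#' binomial sample from the number at risk with the harvest probability of
#' untagged animals.
#'
#' @param year calendar year of each record.
#' @param age_class one of `"juvenile"`, `"adult"`, `"pooled"` per record.
#' @param n_at_risk,n_harvested non-negative integer counts with
#'   `n_harvested <= n_at_risk`.
#' @return A data frame of class `telemetry_data`.  Zero rows are allowed
#'   (no auxiliary telemetry contribution).
#' @export
telemetry_data <- function(year = integer(), age_class = character(),
                           n_at_risk = integer(), n_harvested = integer()) {
  n <- length(year)
  if (length(age_class) != n || length(n_at_risk) != n ||
      length(n_harvested) != n) {
    stop("telemetry fields must all have the same length")
  }
  age_class <- as.character(age_class)
  bad <- which(!age_class %in% c("juvenile", "adult", "pooled"))
  if (length(bad)) {
    stop("unknown age_class '", age_class[bad[1L]], "' at row ", bad[1L])
  }
  n_at_risk <- as.integer(n_at_risk)
  n_harvested <- as.integer(n_harvested)
  if (any(n_at_risk < 0) || any(n_harvested < 0)) {
    stop("telemetry counts must be non-negative; row ",
         which(n_at_risk < 0 | n_harvested < 0)[1L])
  }
  bad <- which(n_harvested > n_at_risk)
  if (length(bad)) {
    stop("n_harvested (", n_harvested[bad[1L]], ") exceeds n_at_risk (",
         n_at_risk[bad[1L]], ") at row ", bad[1L])
  }
  structure(
    data.frame(year = as.integer(year), age_class = age_class,
               n_at_risk = n_at_risk, n_harvested = n_harvested),
    class = c("telemetry_data", "data.frame")
  )
}

#' Known-removal data for the two-season turkey model
#'
#' Annual removals taken outside the permitted spring harvest, treated as
#' known constants in the likelihood: spring non-permittee removals (NPR;
#' landowner and youth seasons) by age class and fall harvest by age class.
#' Optionally carries the poult-to-hen productivity index and the fall archer
#' abundance index.  A leading index-only row (all four removal counts `NA`)
#' is allowed so the productivity index of the year before reconstruction
#' begins can be stored.
#'
#' @param year calendar years (strictly increasing).
#' @param spring_npr_juvenile,spring_npr_adult,fall_harvest_juvenile,fall_harvest_adult
#'   non-negative integer removal counts (or all-`NA` for an index-only row).
#' @param poult_hen_ratio,archer_index optional numeric survey indices
#'   (`NA` allowed).
#' @return A data frame of class `removal_data`.
#' @export
removal_data <- function(year, spring_npr_juvenile, spring_npr_adult,
                         fall_harvest_juvenile, fall_harvest_adult,
                         poult_hen_ratio = NULL, archer_index = NULL) {
  year <- as.integer(year)
  n <- length(year)
  if (n && any(diff(year) <= 0)) stop("removal years must be increasing")
  cnt <- cbind(spring_npr_juvenile, spring_npr_adult,
               fall_harvest_juvenile, fall_harvest_adult)
  if (nrow(cnt) != n) stop("removal fields must have one value per year")
  partial <- rowSums(is.na(cnt)) %in% c(1L, 2L, 3L)
  if (any(partial)) {
    stop("removal counts must be all present or all missing; row ",
         which(partial)[1L])
  }
  neg <- which(apply(cnt, 1L, function(r) any(!is.na(r) & r < 0)))
  if (length(neg)) {
    stop("negative removal count at row ", neg[1L], " (year ", year[neg[1L]],
         ")")
  }
  d <- data.frame(
    year = year,
    spring_npr_juvenile = as.integer(spring_npr_juvenile),
    spring_npr_adult = as.integer(spring_npr_adult),
    fall_harvest_juvenile = as.integer(fall_harvest_juvenile),
    fall_harvest_adult = as.integer(fall_harvest_adult),
    poult_hen_ratio = if (is.null(poult_hen_ratio)) NA_real_ else
      as.numeric(poult_hen_ratio),
    archer_index = if (is.null(archer_index)) NA_real_ else
      as.numeric(archer_index)
  )
  structure(d, class = c("removal_data", "data.frame"))
}

#' Model specification for statistical population reconstruction
#'
#' Selects between the four model families discussed throughout: abundance
#' either estimated with the second-stage Horvitz-Thompson estimator (`"HT"`)
#' or with initial cohort abundances as likelihood parameters (`"AA"`), and
#' demographic rates either carrying temporal random effects (`"RE"`) or
#' fixed effects only (`"FE"`).
#'
#' The fixed-effects absolute-abundance model (`AA` + `FE`) is numerically
#' unstable without the auxiliary catch-effort likelihood, and is therefore
#' refused unless `catch_effort = TRUE`.
#'
#' @param abundance `"HT"` or `"AA"`.
#' @param effects `"RE"` or `"FE"`.
#' @param catch_effort logical; include the auxiliary catch-effort binomial
#'   likelihood (total annual harvest as a binomial sample of total annual
#'   abundance)?
#' @param re_survival,re_vulnerability logical; which processes carry random
#'   effects when `effects = "RE"`.
#' @return An object of class `spr_model_spec`.
#' @export
model_spec <- function(abundance = c("HT", "AA"), effects = c("RE", "FE"),
                       catch_effort = FALSE, re_survival = TRUE,
                       re_vulnerability = TRUE) {
  abundance <- match.arg(abundance)
  effects <- match.arg(effects)
  if (abundance == "AA" && effects == "FE" && !catch_effort) {
    stop("the AA_FE model requires the catch-effort auxiliary likelihood ",
         "(catch_effort = TRUE): without it the cohort structure does not ",
         "support stable optimization")
  }
  if (effects == "FE") re_survival <- re_vulnerability <- FALSE
  if (effects == "RE" && !re_survival && !re_vulnerability) {
    stop("an RE model must place a random effect on at least one process")
  }
  structure(
    list(abundance = abundance, effects = effects,
         catch_effort = isTRUE(catch_effort),
         re_survival = isTRUE(re_survival),
         re_vulnerability = isTRUE(re_vulnerability)),
    class = "spr_model_spec"
  )
}

#' @export
print.spr_model_spec <- function(x, ...) {
  cat("SPR model ", x$abundance, "_", x$effects,
      if (x$catch_effort) " + catch-effort auxiliary", "\n", sep = "")
  if (x$effects == "RE") {
    cat("  random effects on:",
        paste(c("survival", "vulnerability")[c(x$re_survival,
                                               x$re_vulnerability)],
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Shorthand model code, e.g. "HT_RE"
#' @param spec an `spr_model_spec`.
#' @return character scalar.
#' @export
model_code <- function(spec) paste(spec$abundance, spec$effects, sep = "_")
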