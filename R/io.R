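#' Read age-at-harvest data from CSV
#'
#' Expects a comma-separated file with header
#' `year,juvenile_harvest,adult_harvest,effort` (an `effort_se` column is
#' optional), one row per year, years strictly increasing and contiguous.
#' Plain UTF-8, `.` decimal separator, no thousands separators.
#'
#' @param path file path.
#' @return An [aah_data()] object.
#' @export
read_age_at_harvest <- function(path) {
  d <- read_checked(path, c("year", "juvenile_harvest", "adult_harvest",
                            "effort"))
  aah_data(years = d$year, juvenile_harvest = d$juvenile_harvest,
           adult_harvest = d$adult_harvest, effort = d$effort,
           effort_se = d$effort_se)
}

#' Write age-at-harvest data to CSV
#' @param data an [aah_data()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_age_at_harvest <- function(data, path) {
  stopifnot(inherits(data, "aah_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read radiotelemetry records from CSV
#'
#' Header `year,age_class,n_at_risk,n_harvested`.  A file with a header and
#' no rows is a valid empty telemetry set (no auxiliary contribution).
#'
#' @param path file path.
#' @return A [telemetry_data()] object.
#' @export
read_telemetry <- function(path) {
  d <- read_checked(path, c("year", "age_class", "n_at_risk", "n_harvested"),
                    allow_empty = TRUE)
  telemetry_data(year = d$year, age_class = d$age_class,
                 n_at_risk = d$n_at_risk, n_harvested = d$n_harvested)
}

#' Write radiotelemetry records to CSV
#' @param telemetry a [telemetry_data()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(telemetry, path) {
  stopifnot(inherits(telemetry, "telemetry_data"))
  utils::write.csv(as.data.frame(telemetry), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read known-removal data from CSV
#'
#' Header `year,spring_npr_juvenile,spring_npr_adult,fall_harvest_juvenile,`
#' `fall_harvest_adult` with optional `poult_hen_ratio` and `archer_index`
#' columns.  Empty cells are read as `NA` (allowed only for the index columns
#' or for a whole index-only row).
#'
#' @param path file path.
#' @return A [removal_data()] object.
#' @export
read_removals <- function(path) {
  d <- read_checked(path, c("year", "spring_npr_juvenile", "spring_npr_adult",
                            "fall_harvest_juvenile", "fall_harvest_adult"))
  removal_data(year = d$year,
               spring_npr_juvenile = d$spring_npr_juvenile,
               spring_npr_adult = d$spring_npr_adult,
               fall_harvest_juvenile = d$fall_harvest_juvenile,
               fall_harvest_adult = d$fall_harvest_adult,
               poult_hen_ratio = d$poult_hen_ratio,
               archer_index = d$archer_index)
}

#' Write a fitted reconstruction to CSV
#'
#' Emits a single long-format CSV with a `component` column separating
#' parameter estimates (`parameter`), empirical Bayes random-effect
#' predictions (`random_effect`) and the annual abundance series
#' (`abundance`), each with estimate, standard error and 95% confidence
#' limits where available.
#'
#' @param fit an `spr_fit` object from [fit_spr()] or [fit_turkey()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "spr_fit"))
  par_tab <- data.frame(component = "parameter", name = fit$par$name,
                        year = NA_integer_, estimate = fit$par$estimate,
                        se = fit$par$se, lcl = NA_real_, ucl = NA_real_)
  re_tab <- NULL
  if (!is.null(fit$eb_effects) && nrow(fit$eb_effects)) {
    re_tab <- data.frame(component = "random_effect",
                         name = fit$eb_effects$name,
                         year = fit$eb_effects$year,
                         estimate = fit$eb_effects$estimate, se = NA_real_,
                         lcl = NA_real_, ucl = NA_real_)
  }
  ab <- fit$abundance
  ab_tab <- data.frame(component = "abundance", name = "total",
                       year = ab$year, estimate = ab$estimate, se = ab$se,
                       lcl = ab$lcl, ucl = ab$ucl)
  out <- rbind(par_tab, re_tab, ab_tab)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared CSV reader: checks required columns and reports malformed input with
# row and field names.
read_checked <- function(path, required, allow_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  if (!allow_empty && nrow(d) == 0L) stop("no data rows in ", basename(path))
  d
}

#' East Ozarks male wild turkey data, Missouri, USA, 1996-2010
#'
#' The packaged two-season wild-turkey dataset: spring permitted harvest
#' counts by age class with survey-estimated spring hunter effort (units of
#' 10,000 hunter-trips), known removals (spring non-permittee removals and
#' fall harvest by age class), the poult-to-hen productivity index
#' (1995-2010), the fall archer abundance index, and radiotelemetry records
#' for 1996-2000.
#'
#' The 1997 effort standard error is stored as 0.442 (the printed value has a
#' misplaced separator; every other year's SE lies between 0.3 and 1.0).
#' Effort SEs are metadata only: effort is treated as known in the
#' likelihood.
#'
#' @return A list with elements `aah` ([aah_data()]), `telemetry`
#'   ([telemetry_data()]) and `removals` ([removal_data()], including a 1995
#'   index-only row carrying that year's poult-to-hen ratio).
#' @examples
#' tk <- turkey_data()
#' tk$aah
#' @export
turkey_data <- function() {
  ext <- system.file("extdata", package = "sprgame", mustWork = TRUE)
  list(
    aah = read_age_at_harvest(file.path(ext, "east_ozarks_turkey_aah.csv")),
    telemetry = read_telemetry(file.path(ext, "east_ozarks_turkey_rt.csv")),
    removals = read_removals(file.path(ext, "east_ozarks_turkey_removals.csv"))
  )
}
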