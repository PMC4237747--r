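# Day length and annual photoperiod variation as functions of latitude.
#
# Day length follows the standard sunrise-equation model with a geometric
# horizon: solar declination delta = -23.44 * cos(360 * (d + 10) / 365)
# degrees on day d, hour angle omega from cos(omega) = -tan(lat) * tan(delta),
# day length 2 * omega / 15 hours. Inside the polar circles cos(omega) leaves
# [-1, 1] and the day is clamped to 0 h (polar night) or 24 h (polar day).
# No atmospheric refraction or twilight correction is applied: every
# downstream statistic is rank-based in latitude, and any monotone-in-|lat|
# day-length model yields identical ranks.

DEG <- pi / 180

#' Day length from latitude and day of year
#'
#' @param latitude latitude in degrees, in \[-90, 90\].
#' @param day_of_year integer day of a 365-day year (1--365); vectorized.
#' @return day length in hours, in \[0, 24\].
#' @examples
#' day_length(0, 172)    # ~12 h at the equator
#' day_length(80, 172)   # 24 h, polar day
#' @export
day_length <- function(latitude, day_of_year) {
  stopifnot(length(latitude) == 1L, is.finite(latitude))
  if (abs(latitude) > 90) stopf("latitude %g outside [-90, 90]", latitude)
  stopifnot(all(day_of_year >= 1), all(day_of_year <= 365))
  decl <- -23.44 * cos(2 * pi * (day_of_year + 10) / 365)
  cos_omega <- -tan(latitude * DEG) * tan(decl * DEG)
  out <- numeric(length(cos_omega))
  out[cos_omega >= 1] <- 0                       # polar night
  out[cos_omega <= -1] <- 24                     # polar day
  mid <- cos_omega > -1 & cos_omega < 1
  out[mid] <- 2 * acos(cos_omega[mid]) / DEG / 15
  out
}

#' Annual minimum and maximum day length at a latitude
#'
#' Scans all 365 days of the year; below the polar circles the extremes fall
#' at the solstices, beyond them they clamp to 0 and 24 h.
#'
#' @inheritParams day_length
#' @return named numeric vector `c(min = , max = )` in hours.
#' @export
annual_photoperiod_extremes <- function(latitude) {
  dl <- day_length(latitude, 1:365)
  c(min = min(dl), max = max(dl))
}

#' Annual photoperiod variation (delta-photoperiod)
#'
#' The difference between the annual maximum and minimum day length, in
#' hours: ~0 at the equator, 24 beyond the polar circles, and non-decreasing
#' in |latitude| in between. This is the selective-pressure covariate used by
#' the environmental correlation scan.
#'
#' @inheritParams day_length
#' @return hours, in \[0, 24\].
#' @export
delta_photoperiod <- function(latitude) {
  ext <- annual_photoperiod_extremes(latitude)
  unname(ext["max"] - ext["min"])
}

#' Build an environment table for a set of populations
#'
#' Computes per-population annual minimum/maximum photoperiod and
#' delta-photoperiod from latitude. Extra user-supplied environmental
#' variables (temperature, radiation flux, ...) can be passed through as
#' additional columns; they are carried untouched.
#'
#' @param populations a population table as returned by
#'   [population_table()]: columns `id`, `latitude`, `longitude`,
#'   `n_individuals`.
#' @param extra optional data.frame of additional variables with a
#'   `population_id` column matching `populations$id`.
#' @return data.frame with columns `population_id`, `min_photoperiod`,
#'   `max_photoperiod`, `delta_photoperiod`, plus any pass-through columns.
#' @export
environment_table <- function(populations, extra = NULL) {
  populations <- validate_populations(populations)
  ext <- vapply(populations$latitude, annual_photoperiod_extremes, numeric(2))
  env <- data.frame(
    population_id = populations$id,
    min_photoperiod = ext["min", ],
    max_photoperiod = ext["max", ],
    delta_photoperiod = ext["max", ] - ext["min", ],
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), "population_id" %in% names(extra))
    m <- match(env$population_id, extra$population_id)
    if (anyNA(m)) stopf("extra variables missing for population '%s'",
                        env$population_id[which(is.na(m))[1]])
    env <- cbind(env, extra[m, setdiff(names(extra), "population_id"),
                            drop = FALSE])
  }
  rownames(env) <- NULL
  env
}

#' Write / read an environment table as TSV
#' @param env data.frame from [environment_table()].
#' @param path file path.
#' @return `read_environment_table` returns the data.frame.
#' @export
write_environment_table <- function(env, path) {
  utils::write.table(env, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_environment_table
#' @export
read_environment_table <- function(path) {
  env <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("population_id", "min_photoperiod", "max_photoperiod",
            "delta_photoperiod")
  miss <- setdiff(need, names(env))
  if (length(miss)) stopf("environment table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- with(env, min_photoperiod < 0 | max_photoperiod > 24 |
                min_photoperiod > max_photoperiod)
  if (any(bad)) stopf("photoperiod out of range for population '%s'",
                      env$population_id[which(bad)[1]])
  env
}
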