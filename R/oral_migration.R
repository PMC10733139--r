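# Migration-rate oral exposure for mouthed articles and its inversion:
# the mouthing time needed to reach a given screening estimate.

#' Empirical range of article-to-saliva migration rates
#'
#' Measured migration rates of substances from articles into saliva span
#' 1.7e-6 to 33 micrograms per 10 cm^2 per minute; the highest value is for
#' a PVC article. Rates are stored per 10 cm^2 exactly as reported to avoid
#' a silent factor-of-ten unit error.
#'
#' @return Named numeric vector `c(lowest = 1.7e-6, highest = 33)` in
#'   ug/10 cm^2/min.
#' @export
migration_rate_range <- function() {
  c(lowest = 1.7e-6, highest = 33)
}

#' Create a migration rate record
#'
#' @param rate Migration rate in ug per 10 cm^2 per minute (>= 0).
#' @param material_label Material the rate was measured for.
#' @return An object of class `tra_migration_rate`.
#' @export
migration_rate <- function(rate, material_label = "") {
  check_number(rate, "rate", lower = 0)
  structure(list(rate = as.numeric(rate),
                 material_label = material_label),
            class = "tra_migration_rate")
}

as_rate <- function(rate) {
  if (inherits(rate, "tra_migration_rate")) return(rate$rate)
  check_number(rate, "rate", lower = 0)
  rate
}

#' Oral dose from saliva migration during mouthing
#'
#' dose = rate * (area / 10 cm^2) * mouthing time / body weight, converted
#' from micrograms to mg/kg body weight/day.
#'
#' @param rate A [migration_rate()] or a rate in ug/10 cm^2/min.
#' @param mouthed_area Mouthed surface area in cm^2 (10 cm^2 is the common
#'   mouth-size based value).
#' @param mouthing_time Mouthing time in minutes per day.
#' @param population A [population()] record.
#' @return Daily dose in mg/kg/day.
#' @export
migration_oral_dose <- function(rate, mouthed_area, mouthing_time,
                                population) {
  r <- as_rate(rate)
  check_number(mouthed_area, "mouthed_area", lower = 0)
  check_number(mouthing_time, "mouthing_time", lower = 0)
  stopifnot(inherits(population, "tra_population"))
  r * (mouthed_area / 10) * mouthing_time / 1000 / population$body_weight
}

#' Mouthing time needed to reach a target dose
#'
#' Inverts [migration_oral_dose()]: the daily mouthing time at which
#' migration at the given rate reaches a target screening estimate.
#' Times far above 24 h/day show that the screening assumption of complete
#' ingestion of the mouthed amount is conservative for that rate.
#'
#' @param target_dose Target dose in mg/kg body weight/day.
#' @param rate A [migration_rate()] or a rate in ug/10 cm^2/min (> 0).
#' @param mouthed_area Mouthed surface area in cm^2.
#' @param population A [population()] record.
#' @return Mouthing time in hours per day.
#' @export
mouthing_time_to_reach <- function(target_dose, rate, mouthed_area,
                                   population) {
  r <- as_rate(rate)
  check_number(target_dose, "target_dose", lower = 0)
  check_number(mouthed_area, "mouthed_area", lower = 0,
               strict_lower = TRUE)
  stopifnot(inherits(population, "tra_population"))
  if (r <= 0) {
    tra_abort("migration rate is zero: the target dose is unreachable")
  }
  minutes <- target_dose * 1000 * population$body_weight /
    (r * mouthed_area / 10)
  minutes / 60
}

#' Round a mouthing time for reporting
#'
#' Times below one hour are reported to one decimal, longer times to the
#' nearest whole hour.
#'
#' @param hours Time in hours.
#' @return Rounded hours.
#' @export
report_mouthing_hours <- function(hours) {
  check_number(hours, "hours", lower = 0)
  if (hours < 1) round(hours, 1) else round(hours)
}

#' Thickness equivalent of an ingested volume
#'
#' The volume of article material assumed ingested, expressed as the
#' thickness of a layer over the mouthed area: thickness = volume / area.
#' Ingested volumes of 0.01 to 0.3 cm^3 over the standard 10 cm^2 mouthed
#' area correspond to 0.001 to 0.03 cm.
#'
#' @param ingested_volume cm^3.
#' @param mouthed_area cm^2 (> 0).
#' @return Thickness in cm.
#' @export
implied_uptake_thickness <- function(ingested_volume, mouthed_area) {
  check_number(ingested_volume, "ingested_volume", lower = 0)
  check_number(mouthed_area, "mouthed_area", lower = 0,
               strict_lower = TRUE)
  ingested_volume / mouthed_area
}
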