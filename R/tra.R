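# Core screening-tier route algorithms: vapor-pressure banding, inhalation
# with the saturated-vapor-concentration cap, thickness-layer dermal dose,
# oral ingestion dose, aggregation and weight-fraction rescaling.

R_GAS <- 8.314       # J/(mol K)
T_DEFAULT <- 298.15  # K; the tool does not prescribe a temperature

#' Volatility band table
#'
#' Substances are assigned to one of four volatility bands by vapor
#' pressure; the band's release fraction is the fraction of the substance
#' in the product assumed instantaneously released to room air. Complete
#' release (fraction 1) applies at 10 Pa and higher; each order of
#' magnitude decrease in vapor pressure reduces the fraction released by a
#' factor of 10, down to a floor of 0.001 for the lowest band (< 0.1 Pa).
#' Bounds are lower-inclusive, upper-exclusive.
#'
#' @return A data.frame with columns `lower_pa`, `upper_pa`,
#'   `release_fraction`.
#' @export
vp_bands <- function() {
  data.frame(lower_pa = c(10, 1, 0.1, 0),
             upper_pa = c(Inf, 10, 1, 0.1),
             release_fraction = c(1, 0.1, 0.01, 0.001))
}

#' Assign a vapor pressure to its volatility band
#'
#' @param vapor_pressure Vapor pressure in Pa; must be positive.
#' @return A one-row data.frame from [vp_bands()] (columns `lower_pa`,
#'   `upper_pa`, `release_fraction`).
#' @examples
#' assign_vp_band(10)$release_fraction    # 1
#' assign_vp_band(0.05)$release_fraction  # 0.001
#' @export
assign_vp_band <- function(vapor_pressure) {
  check_number(vapor_pressure, "vapor_pressure", lower = 0,
               strict_lower = TRUE)
  bands <- vp_bands()
  hit <- which(vapor_pressure >= bands$lower_pa &
                 vapor_pressure < bands$upper_pa)
  bands[hit, , drop = FALSE]
}

#' Saturated vapor concentration
#'
#' Ideal-gas upper bound on the airborne mass concentration of a pure
#' substance: SVC = VP * MW / (R * T), returned in mg/m^3. Used as a cap on
#' non-aerosol inhalation estimates.
#'
#' @param substance A [substance()].
#' @param temperature Temperature in K (default 298.15).
#' @return SVC in mg/m^3.
#' @export
saturated_vapor_concentration <- function(substance,
                                          temperature = T_DEFAULT) {
  stopifnot(inherits(substance, "tra_substance"))
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  # Pa * (g/mol) / (J/(mol K) * K) = g/m^3; * 1000 -> mg/m^3
  substance$vapor_pressure * substance$molecular_weight /
    (R_GAS * temperature) * 1000
}

#' Inhalation event-average air concentration
#'
#' Instantaneous-release, well-mixed-room estimate (the lowest-tier box
#' model): all of the released substance mass is assumed present in room
#' air for the duration of the event, so the event average equals the peak
#' `m/V`. The released mass is the product amount times weight fraction
#' times the band release fraction; aerosols release 100\% regardless of
#' vapor pressure. A dilution fraction (default 1) multiplies the
#' concentration. For non-aerosols the result is capped at the saturated
#' vapor concentration and the cap is recorded when it binds.
#'
#' @param scenario An [exposure_scenario()].
#' @param substance A [substance()].
#' @param temperature Temperature in K for the SVC cap.
#' @return A list: `concentration` (mg/m^3, capped), `uncapped` (mg/m^3),
#'   `svc` (mg/m^3, `NA` for aerosols), `release_fraction`, `band`
#'   (one-row band table or `NULL` for aerosols), `caps_applied`
#'   (character, contains `"svc_cap"` when the cap binds).
#' @export
inhalation_event_concentration <- function(scenario, substance,
                                           temperature = T_DEFAULT) {
  stopifnot(inherits(scenario, "tra_scenario"),
            inherits(substance, "tra_substance"))
  if (scenario$room_volume <= 0) {
    tra_abort("room_volume must be positive for the inhalation route")
  }
  amount_mg <- scenario$product_amount * 1000
  if (scenario$is_aerosol) {
    f_rel <- 1
    band <- NULL
  } else {
    band <- assign_vp_band(substance$vapor_pressure)
    f_rel <- band$release_fraction
  }
  c_raw <- amount_mg * scenario$weight_fraction * f_rel *
    scenario$dilution_fraction / scenario$room_volume

  caps <- character()
  svc <- NA_real_
  concentration <- c_raw
  if (!scenario$is_aerosol) {
    svc <- saturated_vapor_concentration(substance, temperature)
    if (c_raw > svc) {
      concentration <- svc
      caps <- "svc_cap"
    }
  }
  list(concentration = concentration, uncapped = c_raw, svc = svc,
       release_fraction = f_rel, band = band, caps_applied = caps)
}

#' Inhalation systemic daily dose
#'
#' dose = C * IR * t * n / BW, in mg/kg body weight/day.
#'
#' @param concentration Event-average air concentration, mg/m^3.
#' @param scenario An [exposure_scenario()]; supplies event duration,
#'   events per day and the population's inhalation rate and body weight.
#' @return Daily dose in mg/kg/day.
#' @export
inhalation_daily_dose <- function(concentration, scenario) {
  stopifnot(inherits(scenario, "tra_scenario"))
  check_number(concentration, "concentration", lower = 0)
  pop <- scenario$population
  if (pop$body_weight <= 0) tra_abort("body_weight must be positive")
  concentration * pop$inhalation_rate * scenario$event_duration *
    scenario$events_per_day / pop$body_weight
}

#' Dermal thickness-layer daily dose
#'
#' The dermal model assumes a uniform thickness layer (TL) of product or
#' article material across the whole skin contact area, with the total
#' amount of substance in that layer available: the areal load is
#' TL * density * WF * TF (mg/cm^2) and the dose is
#' SA * areal_load * n / BW. With the standard TL of 0.01 cm and unit
#' density this implies a dermal load of 10 mg/cm^2.
#'
#' @param scenario An [exposure_scenario()].
#' @return A list: `daily_dose` (mg/kg/day), `areal_load` (mg/cm^2),
#'   `notes` (character; records a non-standard thickness layer).
#' @export
dermal_daily_dose <- function(scenario) {
  stopifnot(inherits(scenario, "tra_scenario"))
  pop <- scenario$population
  if (pop$body_weight <= 0) tra_abort("body_weight must be positive")
  # cm * g/cm^3 = g/cm^2; * 1000 -> mg/cm^2
  areal_load <- scenario$thickness_layer * scenario$contact_density *
    scenario$weight_fraction * scenario$transfer_factor * 1000
  dose <- scenario$skin_contact_area * areal_load *
    scenario$events_per_day / pop$body_weight
  list(daily_dose = dose, areal_load = areal_load,
       notes = attr(scenario, "notes") %||% character())
}

#' Oral ingestion daily dose
#'
#' 100\% of the amount placed in the mouth is assumed ingested:
#' dose = Q * WF * TF * n / BW in mg/kg/day.
#'
#' @param scenario An [exposure_scenario()].
#' @return Daily dose in mg/kg/day.
#' @export
oral_daily_dose <- function(scenario) {
  stopifnot(inherits(scenario, "tra_scenario"))
  pop <- scenario$population
  if (pop$body_weight <= 0) tra_abort("body_weight must be positive")
  scenario$ingested_amount * 1000 * scenario$weight_fraction *
    scenario$transfer_factor * scenario$events_per_day / pop$body_weight
}

#' Construct a per-route exposure result
#'
#' Container for one route's estimate, carrying the event air concentration
#' (inhalation only), the systemic daily dose, any caps applied, the
#' implied exposed mass used by the mass-balance check, and provenance.
#'
#' @param route `"inhalation"`, `"dermal"` or `"oral"`.
#' @param daily_dose Systemic dose, mg/kg body weight/day.
#' @param event_air_concentration mg/m^3 (inhalation only).
#' @param caps_applied Character vector, e.g. `"svc_cap"`.
#' @param provenance List of provenance records (band used, overrides,
#'   notes).
#' @param implied_mass_mg Substance mass this route assigns to exposure in
#'   one event (mg).
#' @param available_mass_mg Substance mass actually present in the product,
#'   A * WF (mg).
#' @param population_label `"adult"` or `"child"`.
#' @param weight_fraction Weight fraction the estimate was computed at
#'   (used by [rescale_weight_fraction()]).
#' @return An object of class `tra_result`.
#' @export
exposure_result <- function(route = c("inhalation", "dermal", "oral"),
                            daily_dose,
                            event_air_concentration = NA_real_,
                            caps_applied = character(),
                            provenance = list(),
                            implied_mass_mg = NA_real_,
                            available_mass_mg = NA_real_,
                            population_label = "adult",
                            weight_fraction = NA_real_) {
  route <- match.arg(route)
  check_number(daily_dose, "daily_dose", lower = 0)
  if (length(caps_applied) && route != "inhalation") {
    tra_abort("caps apply only to the inhalation route")
  }
  structure(
    list(route = route, daily_dose = as.numeric(daily_dose),
         event_air_concentration = as.numeric(event_air_concentration),
         caps_applied = caps_applied, provenance = provenance,
         implied_mass_mg = as.numeric(implied_mass_mg),
         available_mass_mg = as.numeric(available_mass_mg),
         population_label = population_label,
         weight_fraction = as.numeric(weight_fraction)),
    class = "tra_result")
}

#' Assess every route of one scenario
#'
#' Runs the inhalation, dermal and oral algorithms (the dermal and oral
#' routes only where the scenario has skin contact or an ingested amount)
#' and returns the per-route results.
#'
#' @param scenario An [exposure_scenario()].
#' @param substance A [substance()].
#' @param temperature Temperature in K for the SVC cap.
#' @return A named list of [exposure_result()]s.
#' @export
assess_scenario <- function(scenario, substance,
                            temperature = T_DEFAULT) {
  stopifnot(inherits(scenario, "tra_scenario"))
  available <- scenario$product_amount * 1000 * scenario$weight_fraction
  pop <- scenario$population$label
  prov <- list(overrides = attr(scenario, "provenance"))

  results <- list()

  inh <- inhalation_event_concentration(scenario, substance, temperature)
  results$inhalation <- exposure_result(
    "inhalation",
    daily_dose = inhalation_daily_dose(inh$concentration, scenario),
    event_air_concentration = inh$concentration,
    caps_applied = inh$caps_applied,
    provenance = c(prov, list(band = inh$band,
                              release_fraction = inh$release_fraction)),
    implied_mass_mg = scenario$product_amount * 1000 *
      scenario$weight_fraction * inh$release_fraction,
    available_mass_mg = available,
    population_label = pop,
    weight_fraction = scenario$weight_fraction)

  if (scenario$skin_contact_area > 0) {
    derm <- dermal_daily_dose(scenario)
    results$dermal <- exposure_result(
      "dermal", daily_dose = derm$daily_dose,
      provenance = c(prov, list(areal_load = derm$areal_load,
                                notes = derm$notes)),
      implied_mass_mg = scenario$skin_contact_area * derm$areal_load,
      available_mass_mg = available,
      population_label = pop,
      weight_fraction = scenario$weight_fraction)
  }

  if (scenario$ingested_amount > 0) {
    results$oral <- exposure_result(
      "oral", daily_dose = oral_daily_dose(scenario),
      provenance = prov,
      implied_mass_mg = scenario$ingested_amount * 1000 *
        scenario$weight_fraction * scenario$transfer_factor,
      available_mass_mg = available,
      population_label = pop,
      weight_fraction = scenario$weight_fraction)
  }

  results
}

#' Total exposure across routes
#'
#' Each route equation operates independently, so the summed routes can
#' together assign more substance mass to exposure than the product
#' contains (for example complete release to air plus full dermal contact).
#' The exceedance is reported as a flag — an accepted source of
#' conservatism in the screening tool — and never corrected.
#'
#' @param results A list of [exposure_result()]s for one scenario; all must
#'   share the same population.
#' @return A list: `total_daily_dose` (mg/kg/day), `mass_balance_exceeded`
#'   (logical), `implied_mass_mg`, `available_mass_mg`.
#' @export
total_exposure <- function(results) {
  if (!is.list(results) ||
      !all(vapply(results, inherits, TRUE, "tra_result"))) {
    tra_abort("'results' must be a list of exposure_result() objects")
  }
  if (!length(results)) {
    return(list(total_daily_dose = 0, mass_balance_exceeded = FALSE,
                implied_mass_mg = 0, available_mass_mg = NA_real_))
  }
  pops <- unique(vapply(results, `[[`, "", "population_label"))
  if (length(pops) > 1L) {
    tra_abort(sprintf("results mix populations: %s",
                      paste(pops, collapse = ", ")))
  }
  total <- sum(vapply(results, `[[`, 0, "daily_dose"))
  implied <- vapply(results, `[[`, 0, "implied_mass_mg")
  avail <- vapply(results, `[[`, 0, "available_mass_mg")
  implied_sum <- if (all(is.na(implied))) NA_real_ else
    sum(implied, na.rm = TRUE)
  avail_use <- if (all(is.na(avail))) NA_real_ else
    max(avail, na.rm = TRUE)
  exceeded <- !is.na(implied_sum) && !is.na(avail_use) &&
    implied_sum > avail_use
  list(total_daily_dose = total, mass_balance_exceeded = exceeded,
       implied_mass_mg = implied_sum, available_mass_mg = avail_use)
}

#' Rescale an exposure result to a different weight fraction
#'
#' Every route dose (and the uncapped air concentration) is exactly linear
#' in the weight fraction, so an estimate at one weight fraction can be
#' rescaled by `new_wf / old_wf`. A result whose concentration was capped
#' at the saturated vapor concentration is not linear in WF; rescaling it
#' raises an error instructing a full recomputation.
#'
#' @param result An [exposure_result()].
#' @param old_wf Weight fraction the result was computed at (> 0).
#' @param new_wf Target weight fraction.
#' @return The rescaled `tra_result`.
#' @export
rescale_weight_fraction <- function(result, old_wf, new_wf) {
  stopifnot(inherits(result, "tra_result"))
  check_number(old_wf, "old_wf", lower = 0, strict_lower = TRUE, upper = 1)
  check_number(new_wf, "new_wf", lower = 0, upper = 1)
  if ("svc_cap" %in% result$caps_applied) {
    tra_abort(paste("result was capped at the saturated vapor",
                    "concentration and is not linear in the weight",
                    "fraction; recompute the scenario at the new weight",
                    "fraction instead"))
  }
  k <- new_wf / old_wf
  result$daily_dose <- result$daily_dose * k
  if (!is.na(result$event_air_concentration)) {
    result$event_air_concentration <- result$event_air_concentration * k
  }
  if (!is.na(result$implied_mass_mg)) {
    result$implied_mass_mg <- result$implied_mass_mg * k
  }
  if (!is.na(result$available_mass_mg)) {
    result$available_mass_mg <- result$available_mass_mg * k
  }
  result$weight_fraction <- new_wf
  result$provenance <- c(result$provenance,
                         list(rescaled = list(old_wf = old_wf,
                                              new_wf = new_wf)))
  result
}

#' Round a value for reporting
#'
#' Reports round to 3 significant figures (matching the precision screening
#' results are conventionally quoted at); internal computations keep full
#' precision.
#'
#' @param x Numeric.
#' @return `signif(x, 3)`.
#' @export
report_value <- function(x) signif(x, 3)

`%||%` <- function(a, b) if (is.null(a)) b else a
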