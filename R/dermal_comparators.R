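# Alternative dermal-from-article transfer models, behind one interface so
# their estimates can be reported as ratios to the thickness-layer model.

#' Article geometry
#'
#' @param article_thickness Article (slab) thickness L in cm.
#' @param article_surface_area Total article surface area in cm^2.
#' @param skin_contact_area Skin contact area in cm^2.
#' @return An object of class `tra_geometry`.
#' @export
article_geometry <- function(article_thickness, article_surface_area,
                             skin_contact_area) {
  check_number(article_thickness, "article_thickness", lower = 0,
               strict_lower = TRUE)
  check_number(article_surface_area, "article_surface_area", lower = 0,
               strict_lower = TRUE)
  check_number(skin_contact_area, "skin_contact_area", lower = 0,
               strict_lower = TRUE)
  structure(list(article_thickness = as.numeric(article_thickness),
                 article_surface_area = as.numeric(article_surface_area),
                 skin_contact_area = as.numeric(skin_contact_area)),
            class = "tra_geometry")
}

#' Diffusion-layer emission from a slab article
#'
#' Simplified diffusivity model for slab-like articles: the emitted mass
#' per unit area is the article concentration times the mean distance a
#' diffusing molecule travels in the matrix in the contact time,
#' d(t) = sqrt(4 D t / pi) — the mean absolute displacement of 1-D
#' Brownian motion. This equals the exact perfect-sink surface-flux
#' integral for a semi-infinite slab, 2 C0 sqrt(D t / pi), so the model
#' has a built-in analytic oracle. All emitted substance is assumed
#' transferred to skin (no material-skin transfer resistance).
#'
#' By default the travel distance is not capped, reproducing the raw model
#' (which can nominally emit more than the article contains). With
#' `deplete_cap = TRUE` the travel distance is capped at the article
#' thickness, so the emission never exceeds the total content C0 * L per
#' unit area.
#'
#' An optional `absorption_fraction` multiplier (default 1) mirrors
#' implementations that scale the emitted mass by a dermally absorbed
#' fraction; the default retains external-exposure semantics.
#'
#' @param article_concentration C0, g/cm^3.
#' @param diffusion_coefficient D, cm^2/s.
#' @param contact_time t, seconds.
#' @param geometry An [article_geometry()] (supplies the thickness cap).
#' @param deplete_cap Cap the emission at the total content (default
#'   `FALSE`).
#' @param absorption_fraction Fraction of emitted mass counted as exposure,
#'   0..1 (default 1).
#' @return A list: `emission` (mg/cm^2), `travel_depth` (cm, after any
#'   cap), `capped` (logical).
#' @export
diffusion_layer_emission <- function(article_concentration,
                                     diffusion_coefficient,
                                     contact_time, geometry,
                                     deplete_cap = FALSE,
                                     absorption_fraction = 1) {
  check_number(article_concentration, "article_concentration", lower = 0)
  check_number(diffusion_coefficient, "diffusion_coefficient", lower = 0)
  check_number(contact_time, "contact_time", lower = 0)
  check_number(absorption_fraction, "absorption_fraction", lower = 0,
               upper = 1)
  stopifnot(inherits(geometry, "tra_geometry"))
  d <- sqrt(4 * diffusion_coefficient * contact_time / pi)
  capped <- FALSE
  if (deplete_cap && d > geometry$article_thickness) {
    d <- geometry$article_thickness
    capped <- TRUE
  }
  emission <- article_concentration * d * 1000 * absorption_fraction
  list(emission = emission, travel_depth = d, capped = capped)
}

#' Mass-balance dermal estimate for an article
#'
#' Upper-bound approach: the entire substance content of the contacted slab
#' is transferred, mass = C0 * L * area, with the area either the skin
#' contact area or the full article surface area.
#'
#' @param article_concentration C0, g/cm^3.
#' @param geometry An [article_geometry()].
#' @param area_basis `"skin"` or `"article"`.
#' @return Transferred mass in mg per event.
#' @export
mass_balance_dermal <- function(article_concentration, geometry,
                                area_basis = c("skin", "article")) {
  check_number(article_concentration, "article_concentration", lower = 0)
  stopifnot(inherits(geometry, "tra_geometry"))
  area_basis <- match.arg(area_basis)
  area <- if (area_basis == "skin") geometry$skin_contact_area else
    geometry$article_surface_area
  article_concentration * geometry$article_thickness * area * 1000
}

#' Migration-formula dermal estimate (regulatory guidance form)
#'
#' Weight of substance on skin per event (g/m^2) as the product of the
#' concentration of the substance in the article (g/m^3), the article
#' thickness (m), the fraction migrating per unit time (1/h) and the
#' exposure time (h). The formula is a first-order short-time
#' approximation: the product fraction * time must be much less than 1.
#' A validity flag is raised when fraction * time >= 0.1 and the call
#' errors when it reaches 1.
#'
#' @param concentration g/m^3.
#' @param thickness m.
#' @param fraction_migrating Fraction migrating per hour (1/h).
#' @param exposure_time h.
#' @return A list: `mass_per_area` (g/m^2), `validity_flag` (logical,
#'   `TRUE` when fraction * time >= 0.1).
#' @export
tgd_migration <- function(concentration, thickness, fraction_migrating,
                          exposure_time) {
  check_number(concentration, "concentration", lower = 0)
  check_number(thickness, "thickness", lower = 0)
  check_number(fraction_migrating, "fraction_migrating", lower = 0)
  check_number(exposure_time, "exposure_time", lower = 0)
  ft <- fraction_migrating * exposure_time
  if (ft >= 1) {
    tra_abort(sprintf(
      "fraction migrating x exposure time = %g; the formula requires it to be much less than 1",
      ft))
  }
  list(mass_per_area = concentration * thickness * fraction_migrating *
         exposure_time,
       validity_flag = ft >= 0.1)
}

#' Transfer-efficiency dermal estimate (impregnated-material form)
#'
#' Daily dermal exposure from contact with impregnated materials as the
#' product of the material weight per surface area, the weight fraction of
#' the substance in the material, a daily material-to-skin transfer
#' efficiency, and the exposed skin surface area.
#'
#' @param material_areal_weight g material per cm^2.
#' @param weight_fraction Weight fraction of the substance in the material,
#'   0..1.
#' @param daily_transfer_efficiency Fraction of the substance in the
#'   contacted material transferred to skin per day, 0..1.
#' @param skin_area Exposed skin surface area, cm^2.
#' @return Exposure in mg/day.
#' @export
transfer_efficiency_dermal <- function(material_areal_weight,
                                       weight_fraction,
                                       daily_transfer_efficiency,
                                       skin_area) {
  check_number(material_areal_weight, "material_areal_weight", lower = 0)
  check_number(weight_fraction, "weight_fraction", lower = 0, upper = 1)
  check_number(daily_transfer_efficiency, "daily_transfer_efficiency",
               lower = 0, upper = 1)
  check_number(skin_area, "skin_area", lower = 0)
  material_areal_weight * weight_fraction * daily_transfer_efficiency *
    skin_area * 1000
}

#' Compare dermal-from-article models against the thickness-layer estimate
#'
#' Runs every comparator for which the required inputs are available and
#' reports each estimate next to the thickness-layer (TL) dermal dose,
#' with the ratio in log10. Validity notes are carried through: the
#' diffusion-layer model is flagged outside its applicability domain for
#' weight fractions above 2\% (at higher concentrations the substance may
#' alter the matrix diffusivity), and the migration formula's short-time
#' bound is propagated.
#'
#' @param scenario An [exposure_scenario()] (dermal determinants and
#'   population).
#' @param substance A [substance()] with `article_concentration` and,
#'   for the diffusion model, `diffusion_coefficient`.
#' @param geometry An [article_geometry()].
#' @param contact_time_s Diffusion contact time in seconds (default: the
#'   scenario event duration).
#' @param deplete_cap Passed to [diffusion_layer_emission()].
#' @param tgd_fraction_migrating Fraction migrating per hour for the
#'   migration formula (`NA` skips that row).
#' @param material_areal_weight g/cm^2 for the transfer-efficiency model
#'   (`NA` skips that row).
#' @param daily_transfer_efficiency Daily transfer efficiency (default
#'   0.08, the upper of the published carpet/hard-surface values).
#' @return A data.frame with columns `model_name`,
#'   `emitted_mass_per_area_mg_cm2`, `daily_dose_mg_kg_day`,
#'   `log10_ratio_to_tra`, `validity_notes`; the first row is the TL model
#'   itself (ratio 0).
#' @export
compare_dermal_models <- function(scenario, substance, geometry,
                                  contact_time_s = NULL,
                                  deplete_cap = FALSE,
                                  tgd_fraction_migrating = NA_real_,
                                  material_areal_weight = NA_real_,
                                  daily_transfer_efficiency = 0.08) {
  stopifnot(inherits(scenario, "tra_scenario"),
            inherits(substance, "tra_substance"),
            inherits(geometry, "tra_geometry"))
  if (is.null(contact_time_s)) {
    contact_time_s <- scenario$event_duration * 3600
  }
  pop <- scenario$population
  n <- scenario$events_per_day
  sa <- geometry$skin_contact_area

  tra <- dermal_daily_dose(scenario)
  if (tra$daily_dose <= 0) {
    tra_abort("thickness-layer dermal dose is zero; ratios are undefined")
  }

  rows <- list(data.frame(
    model_name = "thickness_layer",
    emitted_mass_per_area_mg_cm2 = tra$areal_load,
    daily_dose_mg_kg_day = tra$daily_dose,
    log10_ratio_to_tra = 0,
    validity_notes = "", stringsAsFactors = FALSE))

  add_row <- function(name, per_area, dose, notes) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model_name = name,
      emitted_mass_per_area_mg_cm2 = per_area,
      daily_dose_mg_kg_day = dose,
      log10_ratio_to_tra = log10(dose / tra$daily_dose),
      validity_notes = notes, stringsAsFactors = FALSE)
  }

  if (!is.na(substance$article_concentration)) {
    c0 <- substance$article_concentration
    if (!is.na(substance$diffusion_coefficient)) {
      notes <- if (scenario$weight_fraction > 0.02) {
        "weight fraction > 2%: outside diffusion-model applicability"
      } else ""
      em <- diffusion_layer_emission(c0, substance$diffusion_coefficient,
                                     contact_time_s, geometry,
                                     deplete_cap = deplete_cap)
      add_row("diffusion_layer", em$emission,
              em$emission * sa * n / pop$body_weight,
              paste0(notes, if (em$capped) {
                if (nzchar(notes)) "; emission capped at article content"
                else "emission capped at article content"
              } else ""))
    }
    mb <- mass_balance_dermal(c0, geometry, "skin")
    add_row("mass_balance", mb / sa, mb * n / pop$body_weight, "")

    if (!is.na(tgd_fraction_migrating)) {
      mig <- tgd_migration(c0 * 1e6, geometry$article_thickness / 100,
                           tgd_fraction_migrating,
                           scenario$event_duration)
      # g/m^2 -> mg/cm^2: * 1000 / 1e4
      per_area <- mig$mass_per_area * 0.1
      add_row("tgd_migration", per_area, per_area * sa * n / pop$body_weight,
              if (mig$validity_flag) {
                "fraction x time >= 0.1: short-time approximation strained"
              } else "")
    }
  }

  if (!is.na(material_areal_weight)) {
    te <- transfer_efficiency_dermal(material_areal_weight,
                                     scenario$weight_fraction,
                                     daily_transfer_efficiency, sa)
    add_row("transfer_efficiency", te / sa, te / pop$body_weight, "")
  }

  do.call(rbind, rows)
}
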