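#' Describe a consumer exposure scenario
#'
#' An exposure scenario collects every determinant of the three route
#' equations for one product category (PC, formulated products) or article
#' category (AC, solid articles): the amount used, the weight fraction of
#' the substance, room volume and durations for inhalation, skin contact
#' area and thickness layer for the dermal route, and the ingested amount
#' and mouthed area for the oral route.
#'
#' Internal units are fixed: amounts in g per event, areas in cm^2, the
#' thickness layer in cm, room volume in m^3, durations in h. Doses are
#' reported in mg/kg body weight/day and air concentrations in mg/m^3.
#'
#' The thickness layer (TL) is the assumed uniform layer of product or
#' article material in skin contact: 0.01 cm for liquids (and articles with
#' prolonged/moist contact such as flooring, car seats, diapers, tissues),
#' 0.001 cm for most other articles, reflecting reduced substance mobility
#' in a solid matrix. Any other value is accepted but recorded as a
#' deviation note in the scenario's provenance.
#'
#' @param category_code Scenario code, e.g. `"PC9a-spray-paint"`.
#' @param scenario_class `"product"` or `"article"`.
#' @param is_aerosol Logical; aerosols release 100\% of the substance to air
#'   regardless of vapor pressure and are never capped at the saturated
#'   vapor concentration.
#' @param product_amount Amount of product (or contacted article mass basis)
#'   in g per event.
#' @param weight_fraction Weight fraction of the substance, 0..1.
#' @param room_volume Room volume in m^3 (default 20, the standard room).
#' @param dilution_fraction Multiplicative dilution fraction on the air
#'   concentration accounting for non-ventilated air flow between rooms,
#'   0..1 (default 1).
#' @param event_duration Exposure event duration in h.
#' @param events_per_day Use events per day (default 1, daily use).
#' @param skin_contact_area Skin contact area in cm^2.
#' @param thickness_layer Thickness layer in cm (see Details).
#' @param contact_density Density of the layer/article in skin contact,
#'   g/cm^3 (default 1; with TL 0.01 cm this implies a dermal load of
#'   10 mg/cm^2).
#' @param transfer_factor Fraction of substance in the contact layer (or of
#'   the mouthed mass) transferred, 0..1 (default 1).
#' @param ingested_amount Amount placed in the mouth and assumed fully
#'   ingested, g per event (default 0).
#' @param mouthed_area Surface area of the object placed in the mouth,
#'   cm^2 (default 10, based on mouth size).
#' @param population A [population()] record (default adult).
#' @return An object of class `tra_scenario`.
#' @export
exposure_scenario <- function(category_code,
                              scenario_class = c("product", "article"),
                              is_aerosol = FALSE,
                              product_amount = 0,
                              weight_fraction = 0,
                              room_volume = 20,
                              dilution_fraction = 1,
                              event_duration = 1,
                              events_per_day = 1,
                              skin_contact_area = 0,
                              thickness_layer = 0.01,
                              contact_density = 1,
                              transfer_factor = 1,
                              ingested_amount = 0,
                              mouthed_area = 10,
                              population = traconsumer::population("adult")) {
  scenario_class <- match.arg(scenario_class)
  if (!is.character(category_code) || length(category_code) != 1L ||
      !nzchar(category_code)) {
    tra_abort("'category_code' must be a non-empty string")
  }
  if (!is.logical(is_aerosol) || length(is_aerosol) != 1L ||
      is.na(is_aerosol)) {
    tra_abort("'is_aerosol' must be TRUE or FALSE")
  }
  check_number(product_amount, "product_amount", lower = 0)
  check_number(weight_fraction, "weight_fraction", lower = 0, upper = 1)
  check_number(room_volume, "room_volume", lower = 0)
  check_number(dilution_fraction, "dilution_fraction", lower = 0, upper = 1)
  check_number(event_duration, "event_duration", lower = 0)
  check_number(events_per_day, "events_per_day", lower = 0)
  check_number(skin_contact_area, "skin_contact_area", lower = 0)
  check_number(thickness_layer, "thickness_layer", lower = 0)
  check_number(contact_density, "contact_density", lower = 0,
               strict_lower = TRUE)
  check_number(transfer_factor, "transfer_factor", lower = 0, upper = 1)
  check_number(ingested_amount, "ingested_amount", lower = 0)
  check_number(mouthed_area, "mouthed_area", lower = 0)
  if (!inherits(population, "tra_population")) {
    tra_abort("'population' must be a population() record")
  }

  notes <- character()
  if (!thickness_layer %in% c(0.01, 0.001)) {
    notes <- c(notes, sprintf(
      "thickness_layer %g cm deviates from the standard values 0.01/0.001 cm",
      thickness_layer))
  }

  structure(
    list(category_code = category_code,
         scenario_class = scenario_class,
         is_aerosol = is_aerosol,
         product_amount = as.numeric(product_amount),
         weight_fraction = as.numeric(weight_fraction),
         room_volume = as.numeric(room_volume),
         dilution_fraction = as.numeric(dilution_fraction),
         event_duration = as.numeric(event_duration),
         events_per_day = as.numeric(events_per_day),
         skin_contact_area = as.numeric(skin_contact_area),
         thickness_layer = as.numeric(thickness_layer),
         contact_density = as.numeric(contact_density),
         transfer_factor = as.numeric(transfer_factor),
         ingested_amount = as.numeric(ingested_amount),
         mouthed_area = as.numeric(mouthed_area),
         population = population),
    class = "tra_scenario",
    notes = notes,
    provenance = list())
}

#' @export
print.tra_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s (%s%s): A %g g, WF %g, V %g m3, t %g h\n",
              x$category_code, x$scenario_class,
              if (x$is_aerosol) ", aerosol" else "",
              x$product_amount, x$weight_fraction, x$room_volume,
              x$event_duration))
  invisible(x)
}

# fields serialisable to/from flat registry rows, with unit-suffixed
# external column names
scenario_columns <- function() {
  c(category_code = "category_code",
    scenario_class = "scenario_class",
    is_aerosol = "is_aerosol",
    product_amount = "product_amount_g",
    weight_fraction = "weight_fraction",
    room_volume = "room_volume_m3",
    dilution_fraction = "dilution_fraction",
    event_duration = "event_duration_h",
    events_per_day = "events_per_day",
    skin_contact_area = "skin_contact_area_cm2",
    thickness_layer = "thickness_layer_cm",
    contact_density = "contact_density_g_cm3",
    transfer_factor = "transfer_factor",
    ingested_amount = "ingested_amount_g",
    mouthed_area = "mouthed_area_cm2",
    population = "population")
}

valid_provenance_tags <- c("printed-in-paper", "fixture-nonauthoritative",
                           "user")

#' Build a scenario registry
#'
#' A registry maps category codes to default [exposure_scenario()]s, each
#' carrying a provenance tag: `"printed-in-paper"` for entries whose values
#' are anchored in the published description of the tool,
#' `"fixture-nonauthoritative"` for bundled illustrative defaults, and
#' `"user"` for entries supplied at run time.
#'
#' @param scenarios A list of [exposure_scenario()] objects.
#' @param provenance Character vector of tags, recycled to the number of
#'   scenarios (default `"user"`).
#' @return An object of class `tra_registry`.
#' @export
scenario_registry <- function(scenarios, provenance = "user") {
  if (!is.list(scenarios) ||
      !all(vapply(scenarios, inherits, TRUE, "tra_scenario"))) {
    tra_abort("'scenarios' must be a list of exposure_scenario() objects")
  }
  codes <- vapply(scenarios, `[[`, "", "category_code")
  if (anyDuplicated(codes)) {
    tra_abort(sprintf("duplicate category codes: %s",
                      paste(unique(codes[duplicated(codes)]),
                            collapse = ", ")))
  }
  provenance <- rep_len(provenance, length(scenarios))
  bad <- setdiff(provenance, valid_provenance_tags)
  if (length(bad)) {
    tra_abort(sprintf("unknown provenance tag(s): %s",
                      paste(bad, collapse = ", ")))
  }
  names(scenarios) <- codes
  names(provenance) <- codes
  structure(list(entries = scenarios, provenance = provenance),
            class = "tra_registry")
}

#' @export
print.tra_registry <- function(x, ...) {
  cat(sprintf("<scenario registry> %d entries\n", length(x$entries)))
  for (code in names(x$entries)) {
    cat(sprintf("  %-28s [%s]\n", code, x$provenance[[code]]))
  }
  invisible(x)
}

scenario_to_row <- function(scenario, provenance) {
  cols <- scenario_columns()
  row <- lapply(names(cols), function(f) {
    if (f == "population") scenario$population$label else scenario[[f]]
  })
  names(row) <- unname(cols)
  row$provenance <- provenance
  as.data.frame(row, stringsAsFactors = FALSE)
}

row_to_scenario <- function(row, origin) {
  cols <- scenario_columns()
  known <- c(unname(cols), "provenance",
             "body_weight_kg", "inhalation_rate_m3_h")
  unknown <- setdiff(names(row), known)
  if (length(unknown)) {
    tra_abort(sprintf("unknown field(s) in %s: %s", origin,
                      paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(c("category_code", "scenario_class"), names(row))
  if (length(missing)) {
    tra_abort(sprintf("missing required field(s) in %s: %s", origin,
                      paste(missing, collapse = ", ")))
  }
  get_field <- function(ext) {
    if (ext %in% names(row)) row[[ext]] else NULL
  }
  pop_label <- get_field("population")
  if (is.null(pop_label) || is.na(pop_label)) pop_label <- "adult"
  pop <- population(pop_label,
                    body_weight = get_field("body_weight_kg"),
                    inhalation_rate = get_field("inhalation_rate_m3_h"))
  args <- list(population = pop)
  for (f in setdiff(names(cols), "population")) {
    v <- get_field(cols[[f]])
    if (!is.null(v) && !is.na(v)) {
      if (f == "is_aerosol") v <- as.logical(v)
      args[[f]] <- v
    }
  }
  tryCatch(do.call(exposure_scenario, args),
           tra_validation_error = function(e) {
             tra_abort(sprintf("invalid entry '%s' in %s: %s",
                               if (!is.null(args$category_code))
                                 args$category_code else "?",
                               origin, conditionMessage(e)))
           })
}

registry_from_rows <- function(rows, origin) {
  scenarios <- vector("list", nrow(rows))
  provenance <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    row <- as.list(rows[i, , drop = FALSE])
    scenarios[[i]] <- row_to_scenario(row, origin)
    provenance[i] <- if (!is.null(row$provenance) && !is.na(row$provenance)) {
      row$provenance
    } else "user"
  }
  scenario_registry(scenarios, provenance)
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "yaml", "json")))
  switch(tolower(tools::file_ext(path)),
         csv = "csv", json = "json", yaml = , yml = "yaml",
         tra_abort(sprintf("cannot infer format from '%s'; pass 'format'",
                           path)))
}

#' Load a scenario registry from CSV, YAML or JSON
#'
#' CSV files use one row per scenario with unit-suffixed column names
#' (`product_amount_g`, `room_volume_m3`, ...); YAML/JSON use a list of
#' records with the same keys. Unknown fields are rejected by name, and
#' every entry is validated against the scenario invariants.
#'
#' @param path File path.
#' @param format `"csv"`, `"yaml"` or `"json"`; inferred from the file
#'   extension when `NULL`.
#' @return A [scenario_registry()].
#' @export
load_registry <- function(path, format = NULL) {
  if (!file.exists(path)) tra_abort(sprintf("file not found: %s", path))
  format <- guess_format(path, format)
  rows <- switch(format,
    csv = tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE),
      error = function(e) tra_abort(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e)))),
    json = {
      recs <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                       error = function(e) tra_abort(sprintf(
                         "cannot parse %s: %s", path, conditionMessage(e))))
      as.data.frame(recs, stringsAsFactors = FALSE)
    },
    yaml = {
      recs <- tryCatch(yaml::read_yaml(path),
                       error = function(e) tra_abort(sprintf(
                         "cannot parse %s: %s", path, conditionMessage(e))))
      do.call(rbind, lapply(recs, function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
      }))
    })
  if (is.null(rows) || nrow(rows) == 0L) {
    tra_abort(sprintf("no scenario entries in %s", path))
  }
  registry_from_rows(rows, path)
}

#' Write a scenario registry to CSV, YAML or JSON
#'
#' Inverse of [load_registry()]: a written registry reads back equal
#' field-by-field.
#'
#' @param registry A [scenario_registry()].
#' @param path Output path.
#' @param format `"csv"`, `"yaml"` or `"json"`; inferred from the extension
#'   when `NULL`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, format = NULL) {
  stopifnot(inherits(registry, "tra_registry"))
  format <- guess_format(path, format)
  rows <- do.call(rbind, lapply(names(registry$entries), function(code) {
    scenario_to_row(registry$entries[[code]], registry$provenance[[code]])
  }))
  switch(format,
    csv = utils::write.csv(rows, path, row.names = FALSE),
    json = jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA),
    yaml = yaml::write_yaml(
      lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ])), path))
  invisible(path)
}

#' Create an override set (SCED-style refinement)
#'
#' Sector-published refinements (Specific Consumer Exposure Determinants)
#' replace individual scenario defaults. Overrides are applied with
#' [apply_overrides()], which validates the result and records every
#' replaced field in the scenario's provenance. Refined values must remain
#' appropriate for the situation being modeled as a whole; the registry
#' default is left untouched.
#'
#' @param category_code Code of the scenario the overrides target.
#' @param values Named list of replacement field values (internal field
#'   names, e.g. `weight_fraction`).
#' @param source Label for the origin of the refinement (e.g. a SCED name).
#' @return An object of class `tra_override_set`.
#' @export
override_set <- function(category_code, values = list(), source = "user") {
  if (!is.character(category_code) || length(category_code) != 1L) {
    tra_abort("'category_code' must be a single string")
  }
  if (!is.list(values) ||
      (length(values) > 0 && is.null(names(values))) ||
      any(names(values) == "")) {
    tra_abort("'values' must be a named list")
  }
  settable <- setdiff(names(scenario_columns()), "category_code")
  bad <- setdiff(names(values), settable)
  if (length(bad)) {
    tra_abort(sprintf("override names not scenario fields: %s",
                      paste(bad, collapse = ", ")))
  }
  structure(list(category_code = category_code, values = values,
                 source = source),
            class = "tra_override_set")
}

#' Apply an override set to a scenario
#'
#' Returns a new scenario in which the overridden fields are replaced and
#' all other fields are unchanged. Each replacement is recorded in the
#' result's provenance (field, old value, new value, source). Applying the
#' same override set twice is idempotent.
#'
#' @param scenario An [exposure_scenario()].
#' @param overrides An [override_set()] targeting the scenario's code.
#' @return The refined `tra_scenario`.
#' @export
apply_overrides <- function(scenario, overrides) {
  stopifnot(inherits(scenario, "tra_scenario"),
            inherits(overrides, "tra_override_set"))
  if (overrides$category_code != scenario$category_code) {
    tra_abort(sprintf("override targets '%s' but scenario is '%s'",
                      overrides$category_code, scenario$category_code))
  }
  if (!length(overrides$values)) return(scenario)

  args <- scenario[setdiff(names(scenario), "category_code")]
  args$category_code <- scenario$category_code
  prov <- attr(scenario, "provenance")
  for (f in names(overrides$values)) {
    old <- if (f == "population") scenario$population else scenario[[f]]
    new <- overrides$values[[f]]
    args[[f]] <- new
    if (!identical(old, new)) {
      prov[[f]] <- list(field = f, old = old, new = new,
                        source = overrides$source)
    }
  }
  out <- do.call(exposure_scenario, args)
  attr(out, "provenance") <- prov
  out
}

#' Retrieve a scenario from a registry
#'
#' @param registry A [scenario_registry()].
#' @param code Category code.
#' @return The `tra_scenario` for `code`; unknown codes raise a validation
#'   error listing the nearest codes.
#' @export
registry_scenario <- function(registry, code) {
  stopifnot(inherits(registry, "tra_registry"))
  if (!code %in% names(registry$entries)) {
    near <- names(registry$entries)[
      order(utils::adist(code, names(registry$entries)))]
    tra_abort(sprintf("unknown scenario code '%s'; nearest: %s", code,
                      paste(utils::head(near, 3), collapse = ", ")))
  }
  registry$entries[[code]]
}
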