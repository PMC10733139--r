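# Orchestration: load substances, run full scenario assessments, and
# write comparison reports. The command-line wrapper in inst/cli is a thin
# shell over these functions.

#' Load substances from CSV or JSON
#'
#' CSV columns (unit-suffixed): `name`, `molecular_weight_g_mol`,
#' `vapor_pressure_pa`, and optionally `density_g_cm3`,
#' `diffusion_coefficient_cm2_s`, `article_concentration_g_cm3`. JSON is a
#' list of records with the same keys.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   `NULL`.
#' @return A list of [substance()] objects, named by substance name.
#' @export
load_substances <- function(path, format = NULL) {
  if (!file.exists(path)) tra_abort(sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json",
                     tra_abort(sprintf(
                       "cannot infer format from '%s'; pass 'format'", path)))
  }
  rows <- switch(match.arg(format, c("csv", "json")),
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path),
                         stringsAsFactors = FALSE))
  known <- c("name", "molecular_weight_g_mol", "vapor_pressure_pa",
             "density_g_cm3", "diffusion_coefficient_cm2_s",
             "article_concentration_g_cm3")
  unknown <- setdiff(names(rows), known)
  if (length(unknown)) {
    tra_abort(sprintf("unknown substance field(s) in %s: %s", path,
                      paste(unknown, collapse = ", ")))
  }
  need <- setdiff(known[1:3], names(rows))
  if (length(need)) {
    tra_abort(sprintf("missing substance field(s) in %s: %s", path,
                      paste(need, collapse = ", ")))
  }
  opt <- function(row, col) {
    if (col %in% names(rows) && !is.na(row[[col]])) row[[col]] else NA_real_
  }
  subs <- lapply(seq_len(nrow(rows)), function(i) {
    row <- rows[i, , drop = FALSE]
    substance(row$name, row$molecular_weight_g_mol, row$vapor_pressure_pa,
              density = opt(row, "density_g_cm3"),
              diffusion_coefficient = opt(row, "diffusion_coefficient_cm2_s"),
              article_concentration = opt(row, "article_concentration_g_cm3"))
  })
  names(subs) <- vapply(subs, `[[`, "", "name")
  subs
}

#' Path to the bundled non-authoritative fixture registry
#'
#' The bundled registry ships illustrative scenario defaults for exercising
#' the tool; except for a handful of published anchor values (the 20 m^3
#' room, the flooring weight fraction of 10\%, the 10 cm^2 mouthed area,
#' thickness-layer assignments) its entries are synthetic and tagged
#' `fixture-nonauthoritative`. Screening decisions should never rely on
#' them.
#'
#' @return File path to the bundled CSV registry.
#' @export
fixture_registry_path <- function() {
  system.file("extdata", "scenarios_fixture.csv", package = "traconsumer",
              mustWork = TRUE)
}

#' Path to the bundled synthetic substances file
#'
#' @return File path to the bundled CSV substance table (synthetic
#'   records spanning the volatility bands).
#' @export
fixture_substances_path <- function() {
  system.file("extdata", "substances_synthetic.csv",
              package = "traconsumer", mustWork = TRUE)
}

result_row <- function(code, result) {
  data.frame(
    category_code = code,
    route = result$route,
    event_air_concentration_mg_m3 =
      report_value(result$event_air_concentration),
    daily_dose_mg_kg_day = report_value(result$daily_dose),
    caps_applied = paste(result$caps_applied, collapse = ";"),
    provenance = paste(names(Filter(Negate(is.null),
                                    result$provenance$overrides)),
                       collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Run a full screening assessment for one or more scenarios
#'
#' For each scenario code, computes the three route estimates and the
#' total with the mass-balance flag, and returns (and optionally writes)
#' a report with one row per route plus a total row.
#'
#' @param registry A [scenario_registry()] or a path to one.
#' @param substance A [substance()], or a list of them keyed by name, or a
#'   path to a substance file (first substance is used unless
#'   `substance_name` selects one).
#' @param codes Character vector of scenario codes to assess.
#' @param substance_name Optional name selecting a substance from a list
#'   or file.
#' @param overrides Optional list of [override_set()]s, applied to
#'   matching scenarios.
#' @param temperature K for the SVC cap.
#' @param out Optional output path (written via [write_report()]).
#' @param format `"csv"` or `"json"` for `out`.
#' @return A data.frame report, invisibly when `out` is given. Reported
#'   numbers are rounded to 3 significant figures.
#' @export
run_assessment <- function(registry, substance, codes,
                           substance_name = NULL, overrides = NULL,
                           temperature = T_DEFAULT, out = NULL,
                           format = c("csv", "json")) {
  if (is.character(registry)) registry <- load_registry(registry)
  stopifnot(inherits(registry, "tra_registry"))
  if (is.character(substance)) substance <- load_substances(substance)
  if (is.list(substance) && !inherits(substance, "tra_substance")) {
    substance <- if (is.null(substance_name)) substance[[1L]] else {
      if (!substance_name %in% names(substance)) {
        tra_abort(sprintf("substance '%s' not found", substance_name))
      }
      substance[[substance_name]]
    }
  }
  stopifnot(inherits(substance, "tra_substance"))
  format <- match.arg(format)

  reports <- lapply(codes, function(code) {
    scenario <- registry_scenario(registry, code)
    if (!is.null(overrides)) {
      for (ov in overrides) {
        if (ov$category_code == code) {
          scenario <- apply_overrides(scenario, ov)
        }
      }
    }
    results <- assess_scenario(scenario, substance, temperature)
    total <- total_exposure(results)
    rows <- do.call(rbind, lapply(results, function(r) {
      result_row(code, r)
    }))
    total_row <- data.frame(
      category_code = code, route = "total",
      event_air_concentration_mg_m3 = NA_real_,
      daily_dose_mg_kg_day = report_value(total$total_daily_dose),
      caps_applied = if (total$mass_balance_exceeded) {
        "mass_balance_exceeded"
      } else "",
      provenance = "", stringsAsFactors = FALSE)
    rbind(rows, total_row)
  })
  report <- do.call(rbind, c(reports, list(make.row.names = FALSE)))
  if (!is.null(out)) {
    write_report(report, out, format)
    return(invisible(report))
  }
  report
}

#' Write a report data.frame as CSV or JSON
#'
#' The two formats carry identical values; JSON is a list of row records.
#'
#' @param report A data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  switch(format,
    csv = utils::write.csv(report, path, row.names = FALSE, na = ""),
    json = jsonlite::write_json(report, path, auto_unbox = TRUE,
                                digits = NA, na = "null"))
  invisible(path)
}

#' Run one of the comparison harnesses
#'
#' Modes:
#' \describe{
#'   \item{`dermal`}{[compare_dermal_models()] for one scenario, substance
#'     and geometry.}
#'   \item{`vp_sweep`}{[vp_sweep()] of band versus mechanistic release
#'     fractions.}
#'   \item{`oral_mouthing`}{[mouthing_time_to_reach()] for a vector of
#'     target doses at one migration rate.}
#' }
#'
#' @param mode One of `"dermal"`, `"vp_sweep"`, `"oral_mouthing"`.
#' @param ... Arguments passed to the mode's function. For
#'   `oral_mouthing`: `targets` (numeric vector of doses, mg/kg/day),
#'   `rate`, `mouthed_area` (default 10), `population` (default child).
#' @param out Optional output path.
#' @param format `"csv"` or `"json"`.
#' @return The comparison data.frame.
#' @export
run_comparison <- function(mode = c("dermal", "vp_sweep", "oral_mouthing"),
                           ..., out = NULL, format = c("csv", "json")) {
  mode <- match.arg(mode)
  args <- list(...)
  tab <- switch(mode,
    dermal = do.call(compare_dermal_models, args),
    vp_sweep = do.call(vp_sweep, args),
    oral_mouthing = {
      targets <- args$targets
      if (is.null(targets)) {
        tra_abort("oral_mouthing mode needs 'targets' (doses, mg/kg/day)")
      }
      rate <- args$rate %||%
        tra_abort("oral_mouthing mode needs 'rate' (ug/10cm2/min)")
      area <- args$mouthed_area %||% 10
      pop <- args$population %||% population("child")
      hours <- vapply(targets, mouthing_time_to_reach, 0, rate = rate,
                      mouthed_area = area, population = pop)
      data.frame(target_dose_mg_kg_day = targets,
                 mouthing_hours = hours,
                 mouthing_hours_reported =
                   vapply(hours, report_mouthing_hours, 0))
    })
  if (!is.null(out)) write_report(tab, out, match.arg(format))
  tab
}
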