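#' Create a substance record
#'
#' A substance is described by the physicochemical properties that drive the
#' screening algorithms: molecular weight and vapor pressure feed the
#' volatility banding and the saturated vapor concentration cap; density,
#' diffusion coefficient and the concentration in an article matrix feed the
#' article comparator models.
#'
#' Units are fixed at the type level and never converted inside algorithms:
#' molecular weight in g/mol, vapor pressure in Pa, density in g/cm^3,
#' diffusion coefficient in cm^2/s, article concentration in g/cm^3.
#'
#' @param name Substance label.
#' @param molecular_weight Molecular weight in g/mol; must be positive.
#' @param vapor_pressure Vapor pressure in Pa; must be non-negative.
#' @param density Density in g/cm^3 (optional; positive when set).
#' @param diffusion_coefficient Diffusion coefficient in the article matrix,
#'   cm^2/s (optional, used by the diffusion-layer comparator).
#' @param article_concentration Mass concentration of the substance in the
#'   article matrix, g/cm^3 (optional, used by article comparators).
#' @return An object of class `tra_substance`.
#' @examples
#' substance("limonene", molecular_weight = 136.2, vapor_pressure = 192)
#' @export
substance <- function(name, molecular_weight, vapor_pressure,
                      density = NA_real_, diffusion_coefficient = NA_real_,
                      article_concentration = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    tra_abort("'name' must be a non-empty string")
  }
  check_number(molecular_weight, "molecular_weight", lower = 0,
               strict_lower = TRUE)
  check_number(vapor_pressure, "vapor_pressure", lower = 0)
  check_number(density, "density", lower = 0, strict_lower = TRUE,
               allow_na = TRUE)
  check_number(diffusion_coefficient, "diffusion_coefficient", lower = 0,
               allow_na = TRUE)
  check_number(article_concentration, "article_concentration", lower = 0,
               allow_na = TRUE)
  structure(
    list(name = name,
         molecular_weight = as.numeric(molecular_weight),
         vapor_pressure = as.numeric(vapor_pressure),
         density = as.numeric(density),
         diffusion_coefficient = as.numeric(diffusion_coefficient),
         article_concentration = as.numeric(article_concentration)),
    class = "tra_substance")
}

#' @export
print.tra_substance <- function(x, ...) {
  cat(sprintf("<substance> %s: MW %.4g g/mol, VP %.4g Pa\n",
              x$name, x$molecular_weight, x$vapor_pressure))
  invisible(x)
}

#' Create a population record
#'
#' Holds the body weight and inhalation rate used to convert event
#' concentrations and contact masses into systemic daily doses. The default
#' body weights are 60 kg for adults and 10 kg for children. Inhalation
#' rates are not part of the screening tool's published core and are set
#' here to plausible light-activity values (1 m^3/h adult, 0.5 m^3/h child);
#' they should be overridden where a scenario prescribes its own rate.
#'
#' @param label `"adult"` or `"child"`.
#' @param body_weight Body weight in kg (default 60 adult, 10 child).
#' @param inhalation_rate Inhalation rate in m^3/h (default 1 adult,
#'   0.5 child).
#' @return An object of class `tra_population`.
#' @export
population <- function(label = c("adult", "child"), body_weight = NULL,
                       inhalation_rate = NULL) {
  label <- match.arg(label)
  if (is.null(body_weight)) {
    body_weight <- if (label == "adult") 60 else 10
  }
  if (is.null(inhalation_rate)) {
    inhalation_rate <- if (label == "adult") 1 else 0.5
  }
  check_number(body_weight, "body_weight", lower = 0, strict_lower = TRUE)
  check_number(inhalation_rate, "inhalation_rate", lower = 0)
  structure(
    list(label = label,
         body_weight = as.numeric(body_weight),
         inhalation_rate = as.numeric(inhalation_rate)),
    class = "tra_population")
}

#' Generate synthetic substances spanning the volatility bands
#'
#' Deterministic fixture generator. Vapor pressures are drawn log-uniformly
#' over 1e-6 to 1e5 Pa, stratified across the four volatility bands in
#' rotation so that even a set of four substances exercises every band.
#' Molecular weight, density and diffusion coefficient are drawn from ranges
#' typical of organic product ingredients and article additives.
#'
#' @param count Number of substances (>= 1).
#' @param seed Integer seed; the same seed always yields the same list.
#' @return A list of [substance()] objects.
#' @export
generate_fixture_substances <- function(count, seed) {
  if (!is.numeric(count) || length(count) != 1L || is.na(count) ||
      count < 1 || count != round(count)) {
    tra_abort("'count' must be an integer >= 1")
  }
  check_number(seed, "seed")
  count <- as.integer(count)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  # band strata on log10(VP/Pa), overall range [-6, 5]
  strata <- list(c(-6, -1), c(-1, 0), c(0, 1), c(1, 5))
  lapply(seq_len(count), function(i) {
    s <- strata[[((i - 1L) %% 4L) + 1L]]
    vp <- 10^stats::runif(1, s[1], s[2])
    substance(
      name = sprintf("synthetic-%03d", i),
      molecular_weight = stats::runif(1, 50, 500),
      vapor_pressure = vp,
      density = stats::runif(1, 0.8, 1.5),
      diffusion_coefficient = 10^stats::runif(1, -14, -8),
      article_concentration = stats::runif(1, 0.001, 0.3))
  })
}
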