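---
title: "Screening-level consumer exposure estimation: models and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening-level consumer exposure estimation: models and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traconsumer)
```

## The screening problem

Regulatory chemical safety assessment needs exposure estimates for
thousands of substance-scenario combinations: substances present in
formulated consumer products (product categories, PCs — paints, cleaners,
glues) and in solid articles (article categories, ACs — flooring, toys,
textiles). A screening (Tier 1) tool must be computable from minimal
input — a use amount, a weight fraction, a handful of scenario defaults —
and must not under-predict: a false negative removes a combination from
further scrutiny. Realism is secondary to that guarantee; combinations
that screen high are passed on to higher-tier models or measurement.

`traconsumer` implements the deterministic route algorithms of such a
screening tool for the inhalation, dermal and oral routes, together with
the comparator models used to benchmark its conservatism: a ventilated
box model and an evaporation-limited emission simulator for inhalation,
four dermal-from-article transfer models, and saliva-migration mouthing
models for the oral route.

## Route algorithms

### Inhalation: volatility bands and the SVC cap

A substance is assigned to one of four volatility bands by vapor
pressure. The band's release fraction $f_{rel}$ is the fraction of the
substance in the product assumed *instantaneously* released and
well-mixed into room air:

| band (Pa)      | $f_{rel}$ |
|----------------|-----------|
| $\ge 10$       | 1         |
| $[1, 10)$      | 0.1       |
| $[0.1, 1)$     | 0.01      |
| $< 0.1$        | 0.001     |

The event-average air concentration is
$C = A \cdot WF \cdot f_{rel} \cdot f_{dil} / V$ with the use amount $A$
(mg), weight fraction $WF$, a dilution fraction $f_{dil}$ (default 1)
for air exchange between unventilated rooms, and room volume $V$
(default 20 m^3). Because the release is instantaneous and the room
unventilated, the event average equals the peak $m/V$; ventilation is
handled only in the comparator box model. The systemic dose is
$C \cdot IR \cdot t \cdot n / BW$.

Two asymmetries are deliberate. Aerosols always use $f_{rel} = 1$,
whatever the vapor pressure. For non-aerosols the concentration is capped
at the saturated vapor concentration,
$SVC = VP \cdot MW / (R\,T)$ (mg/m^3 after unit conversion, $T$
defaulting to 298.15 K since the tool itself prescribes none) — air
cannot hold more vapor than the substance's volatility allows. The cap is
recorded in the result's `caps_applied`, because a capped estimate is no
longer linear in $WF$ and must not be rescaled
(`rescale_weight_fraction()` refuses and demands recomputation).

Band bounds are lower-inclusive: 10 Pa is complete release, and 0.1 Pa
belongs to the 0.01 band, with the 0.001 fraction applying strictly below
0.1 Pa. Published descriptions of the lowest band's edge vary between
0.01 and 0.1 Pa; this implementation uses 0.1 Pa, the value consistent
with the decade rule, and the floor of 0.001 holds no matter how far the
vapor pressure falls — which is exactly why the conservatism margin keeps
growing for semi-volatile substances.

### Dermal: the thickness layer

The dermal model assumes a uniform thickness layer (TL) of product or
article material across the entire skin contact area, all of whose
substance content is available: areal load
$= TL \cdot \rho \cdot WF \cdot TF$ and dose
$= SA \cdot \text{load} \cdot n / BW$. The standard TL is 0.01 cm for
liquids; for most articles it is reduced to 0.001 cm to reflect reduced
substance mobility in a solid matrix, except for articles with
prolonged, intensive or moist contact (cuddly toys, car seats and
flooring, diapers, sanitary towels, tissues) which retain 0.01 cm. With
unit density — the default `contact_density`, chosen because the model's
published load arithmetic only closes at 1 g/cm^3 — TL 0.01 cm implies a
load of 10 mg/cm^2. Other TL values are accepted but recorded as a note
rather than rejected, since refinements legitimately change them.

### Oral: complete ingestion

The oral dose is $Q \cdot WF \cdot TF \cdot n / BW$: 100% of the amount
placed in the mouth is assumed ingested. For articles this is a strong
assumption (it implies total migration out of the mouthed solid), which
is why the mouthing-time inversion below is informative.

### Totals without mass balance

Each route operates independently: the inhalation equation may release
100% of the substance to air while the dermal and oral equations still
consume their full contact masses. `total_exposure()` sums the routes and
sets `mass_balance_exceeded` when the implied route masses exceed
$A \cdot WF$; the exceedance is reported, never corrected — it is an
accepted source of screening conservatism.

## Comparator models

### Ventilated box and the evaporation simulator

`box_event_average()` gives the event average of an instantaneous release
decaying under $q$ air changes per hour:
$\frac{m}{VqT}(1 - e^{-qT})$, continuously reaching $m/V$ as
$q \to 0$, and bounded by $m/V$ for all $q$ — the screening estimate is
the box model's conservative limit.

`evaporation_release_fraction()` is the mechanistic counterpart to the
band fractions. It integrates a film of substance evaporating through a
mass-transfer boundary layer, $\dot m = k_m A_s (SVC - C_{air})$ (a
Langmuir-type driving force), coupled to well-mixed ventilated room air.
The released fraction over the event is compared band-by-band in
`vp_sweep()`. The emission mechanism here is a standard mass-transfer
formulation chosen for this package, not a reproduction of any other
tool's internals; the sweep's purpose is the qualitative property —
under screening-conservative settings the band fraction dominates the
mechanistic fraction everywhere, and the gap in orders of magnitude
widens monotonically as vapor pressure falls below the lowest band's
0.1 Pa cutoff, because the band fraction has a floor of 0.001 while real
evaporation keeps slowing.

Simulator defaults emulate a painting-like use — 10 m^2 of film,
250 g of substance in the film, $k_m$ = 1 m/h (a typical indoor
mass-transfer coefficient), a 20 m^3 room at 0.5 air changes per hour
for a 2 h event. These are illustrative settings declared in
`evaporation_spec()` / `box_model_spec()`, not published tool defaults.
Integration uses `deSolve::lsodar` at relative tolerance $10^{-8}$ with
a root stop at film exhaustion; film + air + vented mass is conserved to
well under $10^{-6}$ relative, and the tests cross-check the adaptive
solution against an independent fixed-step Runge-Kutta integration.

### Dermal-from-article comparators

Four alternatives to the thickness layer are implemented behind one
interface (`compare_dermal_models()`), reporting each estimate and its
log10 ratio to the TL dose:

* **Diffusion layer** (`diffusion_layer_emission()`): emission per area
  $= C_0 \cdot d(t)$ with the mean travel distance
  $d(t) = \sqrt{4Dt/\pi}$ — the mean absolute displacement of 1-D
  Brownian motion. This formulation is chosen because it reproduces the
  exact perfect-sink semi-infinite-slab flux integral
  $2C_0\sqrt{Dt/\pi}$, giving the model a built-in analytic oracle; the
  tests additionally verify it against a numerical PDE surface-flux
  integral to within 1% in the semi-infinite regime. The raw model is
  deliberately uncapped by default — with a service-life travel time it
  can nominally emit more than the article contains, the published
  objection to it — while `deplete_cap = TRUE` bounds the travel depth
  by the article thickness. The model is flagged outside its
  applicability domain above 2% weight fraction, where the substance
  itself alters matrix diffusivity. An `absorption_fraction` multiplier
  (default 1, retaining external-exposure semantics) mirrors
  implementations that add an absorbed fraction.
* **Mass balance** (`mass_balance_dermal()`): the whole substance
  content of the contacted slab, $C_0 \cdot L \cdot$ area, on either a
  skin-area or article-area basis.
* **Migration formula** (`tgd_migration()`): concentration × thickness ×
  fraction migrating per time × exposure time; a first-order short-time
  approximation whose validity flag fires at fraction × time ≥ 0.1 and
  which errors at ≥ 1.
* **Transfer efficiency** (`transfer_efficiency_dermal()`): areal
  material weight × weight fraction × daily transfer efficiency ×
  skin area, with 0.08/day as the default efficiency (the upper of the
  published carpet/hard-surface values).

### Oral migration and mouthing time

Measured article-to-saliva migration rates span $1.7\times10^{-6}$ to
33 µg/10 cm^2/min (`migration_rate_range()`; stored per 10 cm^2 exactly
as reported, to avoid a silent factor-of-ten error — conversion happens
inside the operations). `migration_oral_dose()` turns a rate, mouthed
area and daily mouthing time into a dose; `mouthing_time_to_reach()`
inverts it. At the highest measured rate, reaching screening estimates
of 0.1–4.3 mg/kg/day for a 10 kg child mouthing 10 cm^2 takes 0.5–22
hours of mouthing per day; at the lowest rate, far more than 24 h/day.
Since observed daily mouthing times per article category are typically
under an hour, the complete-ingestion assumption is conservative for
nearly all substance-material combinations. Reported times round to one
decimal under an hour and to whole hours above, matching how such times
are conventionally quoted.

## Scenario registry, overrides and fixtures

Scenario defaults live in a registry (`load_registry()` /
`write_registry()`, CSV/YAML/JSON with unit-suffixed field names) whose
entries carry provenance tags. The bundled registry is explicitly
non-authoritative: apart from a few published anchors (the 20 m^3 room,
10% flooring weight fraction, 10 cm^2 mouthed area, the TL retention
list), its values are synthetic illustrations, and nothing in the test
suite's quantitative checks depends on them. Refinements are applied
through `override_set()` / `apply_overrides()`, which validate the
refined scenario and record every replaced field with its source —
mirroring how sector-specific determinant sets refine screening
defaults, and the accompanying obligation to justify refinements in the
context of the whole scenario (parameters can be correlated; lowering
one without examining the others can be anti-conservative).

`generate_fixture_substances()` draws synthetic substances with
log-uniform vapor pressures over $10^{-6}$–$10^5$ Pa, stratified across
the four bands in rotation so that even four substances exercise every
band. The generator emulates the *spread* of physicochemical properties
(MW 50–500 g/mol, density 0.8–1.5 g/cm^3, matrix diffusivity
$10^{-14}$–$10^{-8}$ cm^2/s), not any real substance inventory: passing
tests demonstrate algorithmic correctness across the input space, not
agreement with measured exposures, for which this package contains no
data.

## Numerical choices and limitations

* Doses in mg/kg body weight/day, concentrations in mg/m^3; all unit
  conversions happen at I/O boundaries, never inside algorithms.
* Default body weights 60 kg (adult) and 10 kg (child). Inhalation rates
  are not part of the published core; the defaults (1 and 0.5 m^3/h) are
  plausible light-activity values and flagged as such.
* Reports round to 3 significant figures; internal values keep full
  precision. Band bounds are lower-inclusive; ties therefore never
  ambiguous.
* The dilution fraction multiplies the concentration (rather than
  inflating the effective volume); with the default of 1 the choice is
  observationally irrelevant, and per-scenario values are a registry
  override.
* Use frequency is fixed at one event per day; infrequent-use
  adjustments are out of scope.
* Out of scope by design: respirable-fraction treatment for sprays,
  dermal absorption/uptake kinetics (all estimates are external
  exposure), a separate dust-ingestion pathway, and surface-film
  equilibrium dermal models.
* Problem sizes used by the test oracles (a 400-cell PDE grid, 5000-step
  fixed-step integration, 25-point volatility sweeps) were chosen so each
  property suite completes in seconds while leaving an order of magnitude
  between oracle discretisation error and the tolerances asserted.
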