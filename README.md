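# traconsumer

Screening-level (Tier 1) estimation of consumer exposure to chemicals in
products and articles, for exposure scientists and risk assessors who need
deliberately conservative first-pass estimates across many
substance-scenario combinations — plus the comparator models used to
benchmark that conservatism.

## The models

For a substance with vapor pressure *VP* and molecular weight *MW* used in
a scenario with amount *A*, weight fraction *WF*, room volume *V*, event
duration *t*, *n* events/day and body weight *BW*:

- **Inhalation** — instantaneous release into a well-mixed room:
  `C = A · WF · f_rel · f_dil / V`, where the release fraction `f_rel`
  comes from four volatility bands (`≥10 Pa → 1`, `[1,10) → 0.1`,
  `[0.1,1) → 0.01`, `<0.1 Pa → 0.001`; aerosols always 1). Non-aerosol
  concentrations are capped at the saturated vapor concentration
  `SVC = VP · MW / (R T)`. Dose `= C · IR · t · n / BW`.
- **Dermal** — a uniform thickness layer TL (0.01 cm liquids, 0.001 cm
  most articles) in full skin contact: areal load
  `= TL · ρ · WF · TF` (10 mg/cm² at the standard TL and unit density),
  dose `= SA · load · n / BW`.
- **Oral** — complete ingestion of the mouthed amount:
  dose `= Q · WF · TF · n / BW`.
- **Total** — routes summed independently, with a flag when the implied
  masses exceed `A · WF` (mass balance is intentionally not conserved).

Comparators: ventilated one-box event average
`m/(VqT)·(1−e^{−qT})`, an evaporation-limited film emission simulator
(`k_m A_s (SVC − C_air)` mass-transfer driving force), diffusion-layer
(`C₀·√(4Dt/π)`), mass-balance (`C₀·L·area`), migration-formula and
transfer-efficiency dermal models for articles, and saliva-migration
mouthing-time inversions for the oral route. See the vignette
`vignettes/screening-exposure-methods.Rmd` for assumptions, defaults and
limitations.

## Worked example

A child's plastic toy scenario from the bundled (illustrative,
non-authoritative) registry, assessed for a bundled synthetic low-volatility
substance (VP 0.05 Pa → lowest band):

```r
library(traconsumer)
run_assessment(fixture_registry_path(), fixture_substances_path(),
               codes = "AC13-toys-plastic", substance_name = "synthetic_lowvol")
#>       category_code      route event_air_concentration_mg_m3 daily_dose_mg_kg_day
#> 1 AC13-toys-plastic inhalation                          0.25               0.0125
#> 2 AC13-toys-plastic     dermal                            NA               1.0000
#> 3 AC13-toys-plastic       oral                            NA               0.4300
#> 4 AC13-toys-plastic      total                            NA               1.4400
```

Reading the rows: 50 g of article at 10% weight fraction in the lowest
volatility band puts 0.1% of its substance content into a 20 m³ room
(0.25 mg/m³; a 10 kg child inhaling 0.5 m³/h for 1 h receives
0.0125 mg/kg/day); 100 cm² of skin contact with a 0.001 cm article layer
at 10% weight fraction gives 1 mg/kg/day; mouthing and fully ingesting
0.043 g of article gives 0.43 mg/kg/day. The total, 1.44 mg/kg/day, sums
the routes without conserving mass.

How long would a child actually have to mouth the article for measured
saliva migration to reach such estimates?

```r
run_comparison("oral_mouthing", targets = c(0.1, 0.43, 4.3), rate = 33)
#>   target_dose_mg_kg_day mouthing_hours mouthing_hours_reported
#> 1                  0.10      0.5050505                     0.5
#> 2                  0.43      2.1717172                     2.0
#> 3                  4.30     21.7171717                    22.0
```

0.5–22 hours of mouthing per day at the *highest* measured migration rate
— against typical observed mouthing times below one hour — which is the
sense in which the complete-ingestion assumption screens conservatively.

A command-line wrapper over the same functions ships in
`inst/cli/tra.R` (subcommands `run`, `bands`, `compare-dermal`,
`sweep-vp`, `mouthing-time`, `fixtures`).

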