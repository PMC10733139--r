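test_that("volatility bands follow the decade rule with a 0.001 floor", {
  bands <- vp_bands()
  expect_equal(nrow(bands), 4)
  expect_setequal(bands$release_fraction, c(1, 0.1, 0.01, 0.001))

  expect_equal(assign_vp_band(10)$release_fraction, 1)
  expect_equal(assign_vp_band(5)$release_fraction, 0.1)
  expect_equal(assign_vp_band(0.05)$release_fraction, 0.001)
  # lower-inclusive boundaries
  expect_equal(assign_vp_band(1)$release_fraction, 0.1)
  expect_equal(assign_vp_band(0.1)$release_fraction, 0.01)
  expect_error(assign_vp_band(0), class = "tra_validation_error")
  expect_error(assign_vp_band(-1), class = "tra_validation_error")

  # decade step and monotonicity over a log grid
  grid <- 10^seq(-6, 5, by = 0.25)
  fr <- vapply(grid, function(v) assign_vp_band(v)$release_fraction, 0)
  expect_true(all(diff(fr) >= 0))
  below_top <- grid < 1  # both v and 10 v stay below the top band
  for (v in grid[below_top & grid >= 1e-3]) {
    f_hi <- assign_vp_band(v)$release_fraction
    f_lo <- assign_vp_band(v / 10)$release_fraction
    if (f_lo > 0.001 || v / 10 >= 0.1) {
      expect_equal(f_hi / f_lo, 10, label = sprintf("vp %g", v))
    }
  }
  # conservatism floor: fraction never drops below 0.001
  expect_equal(assign_vp_band(1e-6)$release_fraction, 0.001)
})

test_that("saturated vapor concentration matches the ideal-gas oracle", {
  # oracle: VP * MW / (R T), Pa g/mol / (J/mol) = g/m^3
  s <- substance("water-like", 18, 2337)
  expect_equal(saturated_vapor_concentration(s, 293.15),
               2337 * 18 / (8.314 * 293.15) * 1000, tolerance = 1e-12)
  expect_equal(round(saturated_vapor_concentration(s, 293.15), -1), 17260)

  s0 <- substance("involatile", 18, 0)
  expect_equal(saturated_vapor_concentration(s0), 0)

  s2 <- substance("heavy", 36, 2337)
  expect_equal(saturated_vapor_concentration(s2, 293.15),
               2 * saturated_vapor_concentration(s, 293.15))
})

test_that("inhalation event concentration implements m/V with banding", {
  sc <- make_scenario(product_amount = 20, weight_fraction = 1)
  res <- inhalation_event_concentration(sc, uncapped_substance())
  expect_equal(res$concentration, 1000)  # 20000 mg / 20 m^3
  expect_equal(res$caps_applied, character())

  # dilution fraction multiplies the concentration
  sc_dil <- make_scenario(product_amount = 20, weight_fraction = 1,
                          dilution_fraction = 0.5)
  expect_equal(
    inhalation_event_concentration(sc_dil, uncapped_substance())$concentration,
    500)

  expect_error(
    inhalation_event_concentration(
      make_scenario(product_amount = 20, weight_fraction = 1,
                    room_volume = 0), uncapped_substance()),
    class = "tra_validation_error")
})

test_that("SVC cap binds only for non-aerosols and is recorded", {
  # SVOC: SVC well below the raw m/V estimate
  svoc <- substance("svoc", 390, 2.5e-5)
  sc <- make_scenario(product_amount = 100, weight_fraction = 1)
  res <- inhalation_event_concentration(sc, svoc)
  expect_equal(res$caps_applied, "svc_cap")
  expect_equal(res$concentration, saturated_vapor_concentration(svoc))
  expect_lt(res$concentration, res$uncapped)

  # aerosols: no cap, release fraction 1 independent of VP
  sc_a <- make_scenario(product_amount = 100, weight_fraction = 1,
                        is_aerosol = TRUE)
  res_a <- inhalation_event_concentration(sc_a, svoc)
  expect_equal(res_a$caps_applied, character())
  expect_equal(res_a$concentration, 100 * 1000 / 20)
  res_a2 <- inhalation_event_concentration(
    sc_a, substance("volatile", 390, 5000))
  expect_equal(res_a$concentration, res_a2$concentration)

  # non-aerosol concentration never exceeds SVC across generated cases
  for (s in generate_fixture_substances(12, seed = 3)) {
    r <- inhalation_event_concentration(sc, s)
    expect_lte(r$concentration, saturated_vapor_concentration(s))
  }
})

test_that("inhalation daily dose is C IR t n / BW", {
  sc <- make_scenario(event_duration = 2,
                      population = population("adult"))
  expect_equal(inhalation_daily_dose(632, sc), 632 * 1 * 2 / 60)
  expect_equal(inhalation_daily_dose(0, sc), 0)

  sc_light <- make_scenario(
    event_duration = 2,
    population = population("adult", body_weight = 30))
  expect_equal(inhalation_daily_dose(632, sc_light),
               2 * inhalation_daily_dose(632, sc))
})

test_that("dermal thickness-layer dose reproduces the 10 mg/cm2 load", {
  sc <- make_scenario(weight_fraction = 1, skin_contact_area = 100)
  d <- dermal_daily_dose(sc)
  expect_equal(d$areal_load, 10)  # 0.01 cm x 1 g/cm^3 x 1 x 1

  sc_tf0 <- make_scenario(weight_fraction = 1, skin_contact_area = 100,
                          transfer_factor = 0)
  expect_equal(dermal_daily_dose(sc_tf0)$daily_dose, 0)

  # article TL reduces the load tenfold
  sc_art <- make_scenario(class = "article", weight_fraction = 1,
                          skin_contact_area = 100,
                          thickness_layer = 0.001)
  expect_equal(dermal_daily_dose(sc_art)$areal_load, 1)

  # non-standard TL carried as a note
  sc_odd <- make_scenario(weight_fraction = 1, skin_contact_area = 100,
                          thickness_layer = 0.02)
  expect_match(dermal_daily_dose(sc_odd)$notes, "thickness_layer")
})

test_that("oral dose is Q WF TF n / BW", {
  sc <- make_scenario(class = "article", weight_fraction = 1,
                      ingested_amount = 0.01,
                      population = population("child"))
  expect_equal(oral_daily_dose(sc), 1)  # 10 mg / 10 kg
  sc0 <- make_scenario(class = "article", weight_fraction = 0,
                       ingested_amount = 0.01,
                       population = population("child"))
  expect_equal(oral_daily_dose(sc0), 0)
  sc2 <- make_scenario(class = "article", weight_fraction = 1,
                       ingested_amount = 0.01, events_per_day = 2,
                       population = population("child"))
  expect_equal(oral_daily_dose(sc2), 2)
})

test_that("route doses are linear in WF, amounts, n and 1/BW when uncapped", {
  set.seed(42)
  for (i in 1:10) {
    base <- list(product_amount = runif(1, 1, 500),
                 weight_fraction = runif(1, 0.05, 0.5),
                 skin_contact_area = runif(1, 10, 2000),
                 ingested_amount = runif(1, 0.001, 0.2),
                 event_duration = runif(1, 0.1, 8),
                 events_per_day = sample(1:3, 1),
                 bw = runif(1, 10, 90))
    build <- function(p) {
      make_scenario(class = "article",
                    product_amount = p$product_amount,
                    weight_fraction = p$weight_fraction,
                    skin_contact_area = p$skin_contact_area,
                    ingested_amount = p$ingested_amount,
                    event_duration = p$event_duration,
                    events_per_day = p$events_per_day,
                    population = population("adult", body_weight = p$bw))
    }
    sub <- uncapped_substance()
    doses <- function(p) {
      sc <- build(p)
      c(inh = inhalation_daily_dose(
          inhalation_event_concentration(sc, sub)$concentration, sc),
        derm = dermal_daily_dose(sc)$daily_dose,
        oral = oral_daily_dose(sc))
    }
    d0 <- doses(base)
    half_wf <- modifyList(base, list(weight_fraction =
                                       base$weight_fraction / 2))
    expect_equal(doses(half_wf), d0 / 2, tolerance = 1e-12)
    dbl_n <- modifyList(base, list(events_per_day =
                                     base$events_per_day * 2))
    expect_equal(doses(dbl_n), d0 * 2, tolerance = 1e-12)
    dbl_bw <- modifyList(base, list(bw = base$bw * 2))
    expect_equal(doses(dbl_bw), d0 / 2, tolerance = 1e-12)
    dbl_amt <- modifyList(base, list(product_amount =
                                       base$product_amount * 2))
    expect_equal(doses(dbl_amt)[["inh"]], 2 * d0[["inh"]],
                 tolerance = 1e-12)
  }
})

test_that("total exposure sums routes and reports mass-balance exceedance", {
  mk <- function(route, dose, implied = NA, avail = NA, pop = "adult") {
    exposure_result(route, dose, implied_mass_mg = implied,
                    available_mass_mg = avail, population_label = pop)
  }
  tot <- total_exposure(list(mk("dermal", 46), mk("inhalation", 26)))
  expect_equal(tot$total_daily_dose, 72)
  tot2 <- total_exposure(list(mk("inhalation", 1.4), mk("dermal", 30)))
  expect_equal(tot2$total_daily_dose, 31.4)
  expect_equal(total_exposure(list())$total_daily_dose, 0)

  expect_error(total_exposure(list(mk("dermal", 1, pop = "adult"),
                                   mk("oral", 1, pop = "child"))),
               class = "tra_validation_error")

  # full release to air plus dermal and oral contact must exceed balance
  sc <- make_scenario(class = "article", product_amount = 10,
                      weight_fraction = 0.5, skin_contact_area = 100,
                      ingested_amount = 0.1)
  res <- assess_scenario(sc, uncapped_substance())  # top band, f_rel 1
  expect_equal(res$inhalation$provenance$release_fraction, 1)
  tot3 <- total_exposure(res)
  expect_true(tot3$mass_balance_exceeded)
  expect_gt(tot3$implied_mass_mg, tot3$available_mass_mg)
})

test_that("weight-fraction rescaling is exact and refuses capped results", {
  r <- exposure_result("inhalation", 51.4, event_air_concentration = 1542,
                       weight_fraction = 0.5)
  out <- rescale_weight_fraction(r, 0.5, 0.1)
  expect_equal(out$daily_dose, 10.28)
  expect_equal(report_value(out$daily_dose), 10.3)
  expect_equal(out$event_air_concentration, 1542 / 5)

  ident <- rescale_weight_fraction(r, 0.5, 0.5)
  expect_equal(ident$daily_dose, r$daily_dose)

  r2 <- exposure_result("dermal", 146, weight_fraction = 0.1)
  expect_equal(rescale_weight_fraction(r2, 0.1, 0.02)$daily_dose, 146 / 5)

  capped <- exposure_result("inhalation", 5, caps_applied = "svc_cap")
  expect_error(rescale_weight_fraction(capped, 0.5, 0.1), "recompute",
               class = "tra_validation_error")
})
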