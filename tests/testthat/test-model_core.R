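test_that("substance and population records enforce their invariants", {
  expect_error(substance("x", molecular_weight = 0, vapor_pressure = 1),
               class = "tra_validation_error")
  expect_error(substance("x", molecular_weight = 100, vapor_pressure = -1),
               class = "tra_validation_error")
  expect_error(substance("x", 100, 1, density = 0),
               class = "tra_validation_error")
  s <- substance("x", 100, 1)
  expect_true(is.na(s$density))

  expect_equal(population("adult")$body_weight, 60)
  expect_equal(population("child")$body_weight, 10)
  expect_error(population("adult", body_weight = 0),
               class = "tra_validation_error")
})

test_that("scenario invariants reject out-of-range determinants", {
  expect_error(make_scenario(weight_fraction = 1.2),
               class = "tra_validation_error")
  expect_error(make_scenario(dilution_fraction = -0.1),
               class = "tra_validation_error")
  expect_error(make_scenario(transfer_factor = 2),
               class = "tra_validation_error")
  expect_error(make_scenario(product_amount = -5),
               class = "tra_validation_error")
  # non-standard thickness layer is a recorded note, not an error
  sc <- make_scenario(thickness_layer = 0.05)
  expect_match(attr(sc, "notes"), "thickness_layer")
})

test_that("fixture substance generation is deterministic and spans bands", {
  a <- generate_fixture_substances(4, seed = 7)
  b <- generate_fixture_substances(4, seed = 7)
  expect_identical(a, b)
  expect_error(generate_fixture_substances(0, 1),
               class = "tra_validation_error")

  fractions <- vapply(a, function(s) {
    assign_vp_band(s$vapor_pressure)$release_fraction
  }, 0)
  expect_gte(length(unique(fractions)), 3)

  many <- generate_fixture_substances(40, seed = 11)
  for (s in many) {
    expect_gt(s$molecular_weight, 0)
    expect_gte(s$vapor_pressure, 1e-6)
    expect_lte(s$vapor_pressure, 1e5)
    expect_gt(s$density, 0)
    expect_gte(s$diffusion_coefficient, 0)
  }
  all_fr <- vapply(many, function(s) {
    assign_vp_band(s$vapor_pressure)$release_fraction
  }, 0)
  expect_setequal(all_fr, c(1, 0.1, 0.01, 0.001))
})

test_that("bundled fixture registry loads with its provenance tags", {
  reg <- load_registry(fixture_registry_path())
  expect_s3_class(reg, "tra_registry")
  expect_gt(length(reg$entries), 5)
  expect_true(all(reg$provenance %in%
                    c("printed-in-paper", "fixture-nonauthoritative")))
  expect_true(any(reg$provenance == "fixture-nonauthoritative"))
  # published anchors present in the seeded entries
  flooring <- registry_scenario(reg, "AC13-flooring")
  expect_equal(flooring$weight_fraction, 0.1)
  expect_equal(flooring$room_volume, 20)
  expect_equal(flooring$mouthed_area, 10)
})

test_that("registry round-trips through csv, json and yaml", {
  reg <- load_registry(fixture_registry_path())
  for (ext in c("csv", "json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_registry(reg, path)
    back <- load_registry(path)
    expect_equal(back$provenance, reg$provenance)
    for (code in names(reg$entries)) {
      expect_equal(back$entries[[code]], reg$entries[[code]],
                   label = paste(ext, code))
    }
  }
})

test_that("registry loading rejects bad files with named fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("category_code,scenario_class,weight_fraction,banana",
               "X1,product,0.5,1"), path)
  expect_error(load_registry(path), "banana",
               class = "tra_validation_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("category_code,scenario_class,weight_fraction",
               "X1,product,1.2"), path2)
  expect_error(load_registry(path2), "weight_fraction",
               class = "tra_validation_error")

  expect_error(load_registry("does-not-exist.csv"),
               class = "tra_validation_error")
  expect_error(scenario_registry(list(make_scenario("A"),
                                      make_scenario("A"))),
               "duplicate", class = "tra_validation_error")
})

test_that("single-entry registry survives an identity round-trip", {
  reg <- scenario_registry(list(make_scenario("ONLY", product_amount = 9,
                                              weight_fraction = 0.5)),
                           provenance = "user")
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- load_registry(path)
  expect_length(back$entries, 1)
  expect_equal(back$entries$ONLY, reg$entries$ONLY)
})

test_that("overrides replace only the named fields and are idempotent", {
  sc <- make_scenario("PC9a", product_amount = 100, weight_fraction = 0.5,
                      skin_contact_area = 428)
  expect_identical(apply_overrides(sc, override_set("PC9a")), sc)

  ov <- override_set("PC9a", list(weight_fraction = 0.1), source = "SCED-x")
  out <- apply_overrides(sc, ov)
  expect_equal(out$weight_fraction, 0.1)
  same <- setdiff(names(sc), c("weight_fraction"))
  expect_equal(out[same], sc[same])

  twice <- apply_overrides(out, ov)
  expect_equal(twice, out)

  # provenance records every replaced field with its source
  prov <- attr(out, "provenance")
  expect_named(prov, "weight_fraction")
  expect_equal(prov$weight_fraction$old, 0.5)
  expect_equal(prov$weight_fraction$new, 0.1)
  expect_equal(prov$weight_fraction$source, "SCED-x")

  expect_error(apply_overrides(sc, override_set("OTHER")),
               class = "tra_validation_error")
  expect_error(
    apply_overrides(sc, override_set("PC9a", list(weight_fraction = 2))),
    class = "tra_validation_error")
  expect_error(override_set("PC9a", list(nonsense = 1)),
               class = "tra_validation_error")
})

test_that("provenance covers every field changed from the default", {
  sc <- make_scenario("AC1", "article", product_amount = 10,
                      weight_fraction = 0.2, skin_contact_area = 100)
  ov <- override_set("AC1", list(weight_fraction = 0.05,
                                 skin_contact_area = 50,
                                 event_duration = 0.5))
  out <- apply_overrides(sc, ov)
  changed <- names(Filter(function(f) !identical(out[[f]], sc[[f]]),
                          stats::setNames(nm = setdiff(names(sc),
                                                       "population"))))
  expect_setequal(names(attr(out, "provenance")), changed)
})
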