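test_that("packaged fixture configuration loads with the stated financials", {
  path <- system.file("extdata", "fixture_config.yaml",
                      package = "silagetea")
  params <- load_config(path)
  expect_s3_class(params, "tea_params")
  expect_equal(params$financial$discount_rate, 0.08)
  expect_equal(params$financial$lifetime, 25L)
  expect_length(validate_tea_params(params), 0)
})

test_that("config validation names the offending path", {
  cfg <- yaml::read_yaml(system.file("extdata", "fixture_config.yaml",
                                     package = "silagetea"))
  bad <- tempfile(fileext = ".yaml")

  cfg2 <- cfg
  cfg2$prices$lipid_biomass_price <- list(kind = "truncated_normal",
                                          mean = 3, sd = 0.75,
                                          lower = 5, upper = 2)
  writeLines(yaml::as.yaml(cfg2), bad)
  expect_error(load_config(bad), "prices\\.lipid_biomass_price")

  cfg3 <- cfg
  cfg3$financial$discount_rate <- NULL
  writeLines(yaml::as.yaml(cfg3), bad)
  expect_error(load_config(bad), "financial\\.discount_rate")

  cfg4 <- cfg
  cfg4$prices$protein_price$kind <- "lognormal"
  writeLines(yaml::as.yaml(cfg4), bad)
  expect_error(load_config(bad), "protein_price")

  expect_error(load_config(tempfile()), "not found")
})

test_that("save/load round trip is the identity on the parameter set", {
  p0 <- generate_fixture(3)
  tmp <- tempfile(fileext = ".yaml")
  save_config(p0, tmp)
  expect_equal(load_config(tmp), p0, tolerance = 1e-12)
})

test_that("fixture generation is seed-deterministic", {
  expect_identical(generate_fixture(5), generate_fixture(5))
  a <- generate_fixture(5)
  b <- generate_fixture(6)
  expect_false(identical(
    vapply(a$equipment, function(e) e$purchase_cost$mean, 0),
    vapply(b$equipment, function(e) e$purchase_cost$mean, 0)))
})

test_that("zero noise collapses every distribution to a point", {
  all_dists <- c(lapply(fx_point$equipment, `[[`, "purchase_cost"),
                 lapply(fx_point$operating, `[[`, "unit_price"),
                 fx_point$prices)
  expect_true(all(vapply(all_dists, `[[`, "", "kind") == "point"))
})

test_that("generated fixtures satisfy distribution invariants throughout", {
  for (seed in 1:5) {
    p <- generate_fixture(seed)
    for (d in c(lapply(p$equipment, `[[`, "purchase_cost"),
                lapply(p$operating, `[[`, "unit_price"),
                p$prices)) {
      expect_s3_class(d, "dist_spec")
      expect_true(d$lower <= d$mean && d$mean <= d$upper)
      if (d$kind == "truncated_normal") {
        expect_gt(d$sd, 0)
        expect_lt(d$lower, d$upper)
        expect_gte(d$lower, 0)
      }
    }
    expect_length(validate_tea_params(p), 0)
  }
})

test_that("fixture calibration hits its target medians at point evaluation", {
  tg <- fixture_targets()
  e1 <- evaluate_point("scenario1", fx)
  e2 <- evaluate_point("scenario2", fx)
  expect_equal(e1$tci, tg[["tci_scenario1"]], tolerance = 1e-9)
  expect_equal(e1$tpc, tg[["tpc_scenario1"]], tolerance = 1e-9)
  expect_equal(e2$tci, tg[["tci_scenario2"]], tolerance = 1e-9)
  expect_equal(e2$tpc, tg[["tpc_scenario2"]], tolerance = 1e-9)
  # within the +/- 10% acceptance band around the anchors a fortiori
  expect_lt(abs(e1$tci - 4.8e6) / 4.8e6, 0.10)

  custom <- generate_fixture(fixture_spec(2, target_medians =
    c(tci_scenario1 = 6e6, tpc_scenario1 = 12e6)))
  ec <- evaluate_point("scenario1", custom)
  expect_equal(ec$tci, 6e6, tolerance = 1e-9)
  expect_equal(ec$tpc, 12e6, tolerance = 1e-9)
})

test_that("infeasible calibration anchors are rejected", {
  expect_error(generate_fixture(fixture_spec(1, target_medians =
    c(tci_scenario1 = 5e6, tci_scenario2 = 4e6))), "infeasible")
  expect_error(generate_fixture(fixture_spec(1, target_medians =
    c(tpc_scenario1 = 1e6))), "infeasible")
})

test_that("parameter-set validation catches broken cross-references", {
  p <- fx
  p$scenarios$scenario1$revenue_streams[["lignin"]] <- "no_such_price"
  expect_match(paste(validate_tea_params(p), collapse = "; "),
               "no_such_price")
  p2 <- fx
  p2$scenarios$scenario2$revenue_streams <-
    p2$scenarios$scenario2$revenue_streams["lignin"]
  expect_match(paste(validate_tea_params(p2), collapse = "; "),
               "scenario2 must include")
})
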