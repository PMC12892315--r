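test_that("required radius inverts the annulus supply equation", {
  # unit annulus: demand exactly one 1-km ring's harvestable output
  expect_equal(required_radius(100 * pi * 25 * 0.3, 25, 0.3, 0), 1)
  expect_equal(required_radius(33333, 25, 0.30, 5),
               sqrt(25 + 33333 / (25 * 0.30 * 100 * pi)), tolerance = 1e-12)
  expect_equal(required_radius(33333, 25, 0.30, 5), 6.257, tolerance = 1e-3)
  # doubling demand from a point source scales the radius by sqrt(2)
  expect_equal(required_radius(2e4, 25, 0.3, 0),
               sqrt(2) * required_radius(1e4, 25, 0.3, 0), tolerance = 1e-12)
  # inversion to machine precision: harvestable annulus area supplies demand
  for (d in c(5e3, 33333, 2e5)) {
    R <- required_radius(d, 25, 0.3, 5)
    supply <- (R^2 - 25) * pi * 100 * 25 * 0.3
    expect_equal(supply, d, tolerance = 1e-12)
  }
  expect_error(required_radius(1e4, 0, 0.3), "> 0")
  expect_error(required_radius(1e4, 25, 0), "> 0")
})

test_that("mean haul distance matches geometry and scales with tortuosity", {
  expect_equal(mean_haul_distance(0, 1, 1), 2 / 3)   # disc centroid distance
  expect_equal(mean_haul_distance(5, 6.257, 1.45), 8.20, tolerance = 1e-2)
  expect_equal(mean_haul_distance(5, 6.257, 1.45),
               1.45 * mean_haul_distance(5, 6.257, 1), tolerance = 1e-12)
  expect_error(mean_haul_distance(5, 5, 1.45), "exceed")
})

test_that("closed-form haul distance agrees with a uniform-annulus sampler", {
  set.seed(42)
  r0 <- 5; R <- 6.257
  # uniform points over the annulus via inverse-CDF on the radial density
  r <- sqrt(runif(2e5, r0^2, R^2))
  expect_equal(mean_haul_distance(r0, R, 1), mean(r), tolerance = 2e-3)
})

test_that("a delivered-cost draw decomposes into farmgate plus haulage", {
  cfg <- catchment_config()
  expect_equal(delivered_cost_draw(cfg, 25, 0.30, 0, 35), 35)
  haul <- mean_haul_distance(5, required_radius(33333, 25, 0.30, 5), 1.45)
  expect_equal(delivered_cost_draw(cfg, 25, 0.30, 1, 35), 35 + haul * 2,
               tolerance = 1e-12)
  expect_equal(delivered_cost_draw(cfg, 25, 0.30, 1, 35), 51.40,
               tolerance = 0.1)
  one_way <- catchment_config(return_trips = FALSE)
  expect_equal(delivered_cost_draw(one_way, 25, 0.30, 1, 35) - 35,
               (delivered_cost_draw(cfg, 25, 0.30, 1, 35) - 35) / 2,
               tolerance = 1e-12)
})

test_that("supply simulation is seed-deterministic and degenerates cleanly", {
  a <- run_supply_simulation(n = 500, seed = 7)
  b <- run_supply_simulation(n = 500, seed = 7)
  expect_identical(a$draws, b$draws)

  pt <- catchment_config(
    land_fraction = dist_point(0.30), yield = dist_point(25),
    transport_rate = dist_point(1), farmgate_price = dist_point(35))
  r <- run_supply_simulation(pt, n = 100, seed = 1)
  expect_equal(r$sd, 0)
  expect_equal(unique(r$draws),
               delivered_cost_draw(pt, 25, 0.30, 1, 35), tolerance = 1e-12)
})

test_that("delivered cost is nondecreasing in plant demand", {
  pt <- function(demand) catchment_config(demand = demand,
    land_fraction = dist_point(0.30), yield = dist_point(25),
    transport_rate = dist_point(1), farmgate_price = dist_point(35))
  costs <- vapply(c(1e4, 33333, 1e5, 5e5), function(d)
    run_supply_simulation(pt(d), n = 1, seed = 1)$mean, 0)
  expect_true(all(diff(costs) > 0))
})

test_that("regional profiles land near their calibrated delivered costs", {
  wales <- run_supply_simulation(region = region_livestock(),
                                 n = 1000, seed = 11)
  expect_lt(abs(wales$mean - 51.47), 19.67)   # inside the mean +/- sd band
  east <- run_supply_simulation(region = region_arable(),
                                n = 1000, seed = 11)
  expect_lt(abs(east$mean - 58.33), 22.66)
  expect_gt(east$mean, wales$mean)
})

test_that("dry-matter basis conversion preserves cost per tonne dry matter", {
  expect_equal(dm_basis_convert(51.47, 0.25, 0.95), 51.47 * 3.8,
               tolerance = 1e-12)
  expect_equal(dm_basis_convert(51.47, 0.25, 0.95), 195.59, tolerance = 1e-2)
  expect_equal(dm_basis_convert(19.67, 0.25, 0.95), 74.75, tolerance = 1e-2)
  expect_equal(dm_basis_convert(42, 0.3, 0.3), 42)
  # round trip and per-tonne-DM invariance
  x <- dm_basis_convert(77, 0.25, 0.95)
  expect_equal(dm_basis_convert(x, 0.95, 0.25), 77, tolerance = 1e-12)
  expect_equal(x / 0.95, 77 / 0.25, tolerance = 1e-12)
  expect_error(dm_basis_convert(10, 0, 0.95), "\\(0, 1\\]")
})
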