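test_that("tornado swing for a price equals the analytic affine slope", {
  tab <- oat_tornado("scenario1", fx)
  expect_s3_class(tab, "tornado_table")
  expect_true(all(diff(tab$swing) <= 0))          # sorted, largest first

  streams <- product_rates(fx$basis, "scenario1")
  slope <- stream_mass(streams, "protein_product") * 1000 *
    oracle_annuity(0.08, 25)
  row <- tab[tab$parameter == "protein_price", ]
  expect_equal(row$low, 10, tolerance = 1e-9)
  expect_equal(row$high, 20, tolerance = 1e-9)
  expect_equal(row$swing, slope * 10, tolerance = 1e-6)

  degen <- oat_tornado("scenario1", fx,
                       parameters = list(tea_parameter("lignin_price",
                                                       0.1, 0.1)))
  expect_equal(degen$swing, 0)
  expect_error(tea_parameter("x", 2, 1), "low > high")
  expect_error(tea_parameter("x", NULL, 1), "bounds")
})

test_that("a cheaper cost of capital raises ENPV", {
  tab <- oat_tornado("scenario1", fx,
    parameters = list(tea_parameter("discount_rate", 0.06, 0.12)))
  expect_gt(tab$enpv_at_low, tab$enpv_at_high)

  sw <- discount_rate_sweep("scenario1", fx)
  expect_true(all(diff(sw$enpv) < 0))
  expect_equal(sw$enpv[sw$discount_rate == 0.08],
               evaluate_point("scenario1", fx)$npv, tolerance = 1e-9)
  one <- discount_rate_sweep("scenario1", fx, r_grid = 0.09)
  expect_equal(nrow(one), 1)
})

test_that("Monte Carlo tornado mode agrees directionally with deterministic", {
  p <- list(tea_parameter("protein_price", 10, 20))
  det <- oat_tornado("scenario1", fx, parameters = p)
  mcm <- oat_tornado("scenario1", fx, parameters = p, method = "mc",
                     mc = mc_config(1000, 4))
  expect_gt(mcm$enpv_at_high, mcm$enpv_at_low)
  expect_equal(mcm$swing, det$swing, tolerance = 0.05)
})

test_that("extraction sweep: sign, dominance and monotonicity", {
  multi <- extraction_sweep("scenario1", fx)
  solo <- extraction_sweep("scenario1", fx, revenue_mode = "protein_only")
  expect_equal(nrow(multi), 16)
  # no protein revenue at zero extraction: value is the cost annuity
  expect_lt(solo$enpv[solo$efficiency == 0], 0)
  ev0 <- evaluate_point("scenario1", fx,
    overrides = list(basis = list(protein_extraction_efficiency = 0)),
    zero_coproducts = TRUE)
  expect_equal(ev0$revenue, 0)
  expect_true(all(multi$enpv >= solo$enpv))
  expect_true(all(diff(multi$enpv) >= 0))
  expect_true(is.na(multi$unit_cost[multi$efficiency == 0]))
})

test_that("marginal extraction gains reproduce the reference table", {
  tab <- enpv_change_table()
  g1 <- marginal_gains(data.frame(range_low = tab$range_low,
                                  range_high = tab$range_high,
                                  enpv_change = tab$scenario1))
  expect_equal(g1$rows$marginal_gain, c(41.7, 41.7, 37.5, 50.0, 43.3))
  expect_equal(g1$average, 42.84, tolerance = 1e-9)
  expect_equal(round(g1$average), 43)

  g2 <- marginal_gains(data.frame(range_low = tab$range_low,
                                  range_high = tab$range_high,
                                  enpv_change = tab$scenario2))
  expect_equal(g2$rows$marginal_gain, c(40.0, 50.0, 37.5, 50.0, 36.7))
  expect_equal(g2$average, 42.84, tolerance = 1e-9)
  expect_equal(round(g2$average), 43)

  expect_gt(g1$sd, 0)
  expect_error(marginal_gains(data.frame(range_low = 1, range_high = 1,
                                         enpv_change = 5)), "zero-width")
  expect_error(marginal_gains(data.frame(range_low = c(0, 4),
                                         range_high = c(3, 6),
                                         enpv_change = c(1, 1))),
               "contiguous")
})

test_that("break-even price equals unit cost for protein-only revenue", {
  be <- breakeven_price("scenario1", fx, include_coproducts = FALSE)
  streams <- product_rates(fx$basis, "scenario1")
  ev <- evaluate_point("scenario1", fx)
  uc <- unit_cost(ev$tci, ev$tpc, stream_mass(streams, "protein_product"),
                  fin_default)
  expect_equal(be, uc, tolerance = 1e-6)

  with_cop <- breakeven_price("scenario1", fx)
  expect_lt(with_cop, be)                 # coproducts lower the break-even
  # the break-even zeroes the deterministic NPV
  expect_equal(evaluate_point("scenario1", fx,
    overrides = list(prices = c(protein_price = with_cop)))$npv, 0,
    tolerance = 1e-4 * abs(ev$npv))
})

test_that("scale sweep shows economies of scale only for exponent < 1", {
  flat <- scale_sweep("scenario1", fx, capacities = c(1000, 5000, 20000),
                      capital_exponent = 1)
  expect_equal(diff(range(flat$unit_cost)), 0, tolerance = 1e-9)
  expect_equal(diff(range(flat$breakeven_price)), 0, tolerance = 1e-6)

  sw <- scale_sweep("scenario1", fx)
  expect_equal(nrow(sw), 7)
  expect_true(all(diff(sw$unit_cost) < 0))
  expect_true(all(diff(sw$enpv) > 0))
  expect_true(all(diff(sw$breakeven_price) < 0))
  # the base capacity reproduces the base-case evaluation
  base <- evaluate_point("scenario1", fx)
  q <- stream_mass(product_rates(fx$basis, "scenario1"), "protein_product")
  sw0 <- scale_sweep("scenario1", fx, capacities = c(q / 2, q))
  expect_equal(sw0$enpv[2], base$npv, tolerance = 1e-9)
  expect_error(scale_sweep("scenario1", fx, capital_exponent = 0), "> 0")
})
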