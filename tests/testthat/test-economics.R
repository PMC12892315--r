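test_that("npv matches the closed-form annuity on constant cashflows", {
  cash <- cashflow_series(rep(10e6, 25), rep(0, 25))
  expect_equal(npv(cash, 0.08, 50e6),
               10e6 * oracle_annuity(0.08, 25) - 50e6, tolerance = 1e-12)
  expect_equal(npv(cash, 0.08, 50e6) / 1e6, 56.75, tolerance = 1e-4)

  zero <- cashflow_series(rep(0, 25), rep(0, 25))
  expect_equal(npv(zero, 0.08, 7e6), -7e6)

  # undiscounted limit
  r0 <- cashflow_series(1:10, rep(0.5, 10))
  expect_equal(npv(r0, 0, 3), sum(1:10 - 0.5) - 3)
  expect_error(npv(cash, -1, 0), "exceed -1")
})

test_that("unit production cost combines annualised capital and TPC", {
  uc <- unit_cost(4.8e6, 14e6, 5000, fin_default)
  expect_equal(uc, (4.8e6 * oracle_crf(0.08, 25) + 14e6) / 5e6,
               tolerance = 1e-12)
  expect_equal(uc, 2.89, tolerance = 1e-3)
  expect_equal(unit_cost(0, 0, 5000, fin_default), 0)
  expect_equal(unit_cost(4.8e6, 14e6, 10000, fin_default), uc / 2)
  expect_error(unit_cost(1e6, 1e6, 0, fin_default), "> 0")
})

test_that("draw summaries use the linear-interpolation quantile convention", {
  s <- summarize_draws(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$ci90_low, 5.95)
  expect_equal(s$ci90_high, 95.05)
  expect_true(s$ci90_low <= s$median && s$median <= s$ci90_high)

  k <- summarize_draws(rep(4.2, 10))
  expect_equal(k$median, 4.2)
  expect_equal(k$mean, 4.2)
  expect_equal(k$sd, 0)

  x <- rnorm(501)
  expect_equal(summarize_draws(-x)$median, -summarize_draws(x)$median)
  expect_error(summarize_draws(numeric(0)), "empty")
})

test_that("degenerate Monte Carlo reproduces the deterministic pipeline", {
  for (sc in c("scenario1", "scenario2")) {
    r <- simulate_scenario(sc, fx_point, mc = mc_config(500, 3))
    ev <- evaluate_point(sc, fx_point)
    expect_identical(unique(r$tci_draws), ev$tci)
    expect_identical(unique(r$tpc_draws), ev$tpc)
    expect_identical(unique(r$npv_draws), ev$npv)
    expect_equal(r$enpv, ev$npv, tolerance = 1e-12)
    expect_equal(r$summaries$npv$sd, 0)
  }
})

test_that("simulation is deterministic under (seed, n, params)", {
  a <- simulate_scenario("scenario1", fx, mc = mc_config(400, 21))
  b <- simulate_scenario("scenario1", fx, mc = mc_config(400, 21))
  expect_identical(a$npv_draws, b$npv_draws)
  c <- simulate_scenario("scenario1", fx, mc = mc_config(400, 22))
  expect_false(identical(a$npv_draws, c$npv_draws))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(simulate_scenario("scenario1", fx, mc = mc_config(50, 9)))
  expect_identical(rnorm(1), before)
})

test_that("ENPV is affine in a price mean with the analytic slope", {
  streams <- product_rates(fx$basis, "scenario1")
  af <- oracle_annuity(0.08, 25)
  slope <- stream_mass(streams, "protein_product") * 1000 * af
  set_price <- function(p, v) { p$prices$protein_price <- dist_point(v); p }
  r_lo <- simulate_scenario("scenario1", set_price(fx, 12),
                            mc = mc_config(2000, 5))
  r_hi <- simulate_scenario("scenario1", set_price(fx, 18),
                            mc = mc_config(2000, 5))
  expect_equal(r_hi$enpv - r_lo$enpv, slope * 6, tolerance = 1e-9)
})

test_that("NPV is strictly decreasing in the discount rate for positive flows", {
  rs <- seq(0.02, 0.20, by = 0.02)
  cash <- cashflow_series(rep(60e6, 25), rep(14e6, 25))
  vals <- vapply(rs, function(r) npv(cash, r, 5e6), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("the median's sampling error follows the root-n law", {
  med <- function(n, seed) simulate_scenario("scenario1", fx,
    mc = mc_config(n, seed))$summaries$npv$median
  seeds <- 1:100
  se_small <- sd(vapply(seeds, function(s) med(150, s), 0))
  se_large <- sd(vapply(seeds + 1000, function(s) med(1350, s), 0))
  # nine-fold n should reduce the standard error about three-fold
  expect_gt(se_small / se_large, 2.0)
  expect_lt(se_small / se_large, 4.5)
})
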