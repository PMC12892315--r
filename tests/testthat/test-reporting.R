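test_that("cumulative probability export sorts draws against i/n", {
  path <- tempfile(fileext = ".csv")
  export_cdf(c(3, 1, 2), path)
  df <- read.csv(path)
  expect_equal(df$value, c(1, 2, 3))
  expect_equal(df$cumulative_probability, c(1, 2, 3) / 3)

  export_cdf(rep(5, 4), path)
  dfc <- read.csv(path)
  expect_equal(dfc$value, rep(5, 4))
  expect_equal(max(dfc$cumulative_probability), 1)

  set.seed(1)
  export_cdf(rnorm(1000), path)
  dfr <- read.csv(path)
  expect_equal(nrow(dfr), 1000)
  expect_true(all(diff(dfr$value) >= 0))
  expect_true(all(diff(dfr$cumulative_probability) > 0))
  expect_equal(dfr$cumulative_probability[1000], 1)
  expect_error(export_cdf(numeric(0), path), "empty")
})

test_that("the fixture command writes a config that loads and validates", {
  out <- file.path(tempdir(), "cli-fixture")
  expect_equal(tea_cli(c("fixture", "--seed", "1", "--out", out)), 0L)
  params <- load_config(file.path(out, "fixture_config.yaml"))
  expect_length(validate_tea_params(params), 0)
  expect_true(file.exists(file.path(out, "manifest.json")))
})

test_that("simulate command writes schema-complete summaries", {
  out <- file.path(tempdir(), "cli-sim")
  cfg <- file.path(out, "cfg.yaml")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  save_config(fx, cfg)
  status <- tea_cli(c("simulate", "--config", cfg, "--scenario", "scenario1",
                      "--n", "500", "--seed", "1", "--out", out))
  expect_equal(status, 0L)
  summ <- jsonlite::read_json(file.path(out, "scenario1_summary.json"))
  expect_true(all(c("tci", "tpc", "npv", "enpv", "p_npv_positive") %in%
                  names(summ)))
  expect_true(all(c("median", "ci90_low", "ci90_high") %in%
                  names(summ$npv)))
  cdf <- read.csv(file.path(out, "scenario1_npv_cdf.csv"))
  expect_equal(nrow(cdf), 500)
})

test_that("sweep commands honour the requested grid", {
  out <- file.path(tempdir(), "cli-sweep")
  cfg <- file.path(out, "cfg.yaml")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  save_config(fx, cfg)
  expect_equal(tea_cli(c("sweep-extraction", "--config", cfg,
                         "--grid", "0:15:16", "--out", out)), 0L)
  sw <- read.csv(file.path(out, "scenario1_extraction_sweep.csv"))
  expect_equal(nrow(sw), 16)
  expect_equal(sw$efficiency, seq(0, 15))
})

test_that("identical config and seed reproduce outputs byte-identically", {
  cfg <- file.path(tempdir(), "det-cfg.yaml")
  save_config(fx, cfg)
  run <- function(dir) {
    tea_cli(c("simulate", "--config", cfg, "--n", "300", "--seed", "5",
              "--out", dir))
    dir
  }
  d1 <- run(file.path(tempdir(), "det-a"))
  d2 <- run(file.path(tempdir(), "det-b"))
  for (f in c("scenario1_summary.json", "scenario1_npv_cdf.csv",
              "scenario1_streams.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("invalid invocations exit nonzero without raising", {
  expect_equal(tea_cli(character(0)), 1L)
  expect_equal(tea_cli("frobnicate"), 1L)
  expect_equal(tea_cli(c("simulate", "--config", tempfile())), 1L)
  cfg <- file.path(tempdir(), "bad-sc.yaml")
  save_config(fx, cfg)
  expect_equal(tea_cli(c("simulate", "--config", cfg,
                         "--scenario", "scenario9")), 1L)
})

test_that("supply command writes per-draw geometry and summary", {
  out <- file.path(tempdir(), "cli-supply")
  cfg <- file.path(out, "cfg.yaml")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  save_config(fx, cfg)
  expect_equal(tea_cli(c("supply", "--config", cfg, "--region", "livestock",
                         "--n", "200", "--seed", "3", "--out", out)), 0L)
  draws <- read.csv(file.path(out, "supply_draws.csv"))
  expect_equal(nrow(draws), 200)
  expect_true(all(c("radius_km", "haul_km", "cost_gbp_per_wet_t") %in%
                  names(draws)))
  summ <- jsonlite::read_json(file.path(out, "supply_summary.json"))
  expect_equal(summ$n, 200)
  expect_gt(summ$mean_dm95, summ$mean)
})
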