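#' Export an empirical cumulative probability curve
#'
#' Writes a two-column CSV (`value`, `cumulative_probability`) of the sorted
#' draws against the empirical CDF `i/n`, the construction used for
#' cumulative NPV probability curves. Both columns are nondecreasing and the
#' final CDF value is 1.
#'
#' @param draws numeric vector, length >= 1.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_cdf <- function(draws, path) {
  if (length(draws) == 0) stop("empty draw vector", call. = FALSE)
  n <- length(draws)
  utils::write.csv(data.frame(value = sort(draws),
                              cumulative_probability = seq_len(n) / n),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a stream table as CSV
#'
#' @param streams a `stream_table` from [product_rates()] or
#'   [extraction_streams()].
#' @param path output CSV path.
#' @param scenario optional scenario label column.
#' @return `path`, invisibly.
#' @export
export_stream_table <- function(streams, path, scenario = NA_character_) {
  stopifnot(inherits(streams, "stream_table"))
  df <- as.data.frame(streams)
  df$scenario <- scenario
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export scenario summaries as JSON
#'
#' Writes the median / 90% CI / mean / sd summaries of TCI, TPC and NPV,
#' the ENPV and the probability of positive NPV for a simulated scenario.
#'
#' @param result a `scenario_result` from [simulate_scenario()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_summary_json <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  jsonlite::write_json(list(
    scenario = result$scenario, n = result$n, seed = result$seed,
    tci = result$summaries$tci, tpc = result$summaries$tpc,
    npv = result$summaries$npv,
    enpv = result$enpv, p_npv_positive = result$p_npv_positive),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_manifest <- function(out_dir, command, config_path, seed, files) {
  manifest <- list(
    command = command,
    config = if (is.null(config_path)) NA_character_ else config_path,
    config_md5 = if (is.null(config_path)) NA_character_
                 else unname(tools::md5sum(config_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("silagetea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = files)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    if (i == length(args))
      stop(sprintf("flag '%s' needs a value", a), call. = FALSE)
    flags[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

parse_grid <- function(text, default) {
  if (is.null(text)) return(default)
  parts <- as.numeric(strsplit(text, ":", fixed = TRUE)[[1]])
  if (length(parts) != 3 || anyNA(parts))
    stop("grid must be given as lo:hi:n", call. = FALSE)
  seq(parts[1], parts[2], length.out = parts[3])
}

#' Command-line entry point
#'
#' Ties the pipeline stages together behind a single command interface.
#' Commands: `simulate` (Monte Carlo scenario run: summaries JSON, NPV
#' cumulative-probability CSV, stream-table CSV), `tornado` (one-at-a-time
#' sensitivity CSV), `sweep-extraction`, `sweep-scale`, `sweep-discount`
#' (sweep CSVs), `supply` (delivered-silage-cost simulation CSV + JSON) and
#' `fixture` (write a seeded fixture configuration). Every run writes a
#' `manifest.json` recording the command, config hash, seed, package
#' version and output files; rerunning with the same config and seed
#' reproduces every numeric output byte-identically.
#'
#' Flags: `--config <path>` (all commands except `fixture`),
#' `--scenario scenario1|scenario2`, `--seed <int>`, `--n <int>`,
#' `--out <dir>`, `--grid lo:hi:n` (sweeps), `--region livestock|arable`
#' (supply), `--draws true` (simulate: also write the raw draw CSV).
#'
#' @param args character vector of command-line arguments; the first is the
#'   command.
#' @return exit status, 0 on success, invisibly.
#' @export
tea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("no command given", call. = FALSE)
    command <- args[1]
    flags <- parse_cli_flags(args[-1])
    out_dir <- if (is.null(flags$out)) "." else flags$out
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop(sprintf("output directory not writable: %s", out_dir),
           call. = FALSE)
    seed <- if (is.null(flags$seed)) 1L else as.integer(flags$seed)
    n <- if (is.null(flags$n)) NULL else as.integer(flags$n)
    scenario <- if (is.null(flags$scenario)) "scenario1" else flags$scenario

    if (command == "fixture") {
      cfg_path <- file.path(out_dir, "fixture_config.yaml")
      save_config(generate_fixture(seed), cfg_path)
      write_manifest(out_dir, command, NULL, seed, basename(cfg_path))
      return(invisible(0L))
    }

    if (is.null(flags$config))
      stop("--config is required", call. = FALSE)
    params <- load_config(flags$config)
    if (!scenario %in% names(params$scenarios))
      stop(sprintf("unknown scenario '%s'", scenario), call. = FALSE)
    files <- character()
    add <- function(name, writer) {
      path <- file.path(out_dir, name)
      writer(path)
      files <<- c(files, name)
    }

    if (command == "simulate") {
      res <- simulate_scenario(scenario, params,
        mc = mc_config(n_draws = if (is.null(n)) 10000 else n, seed = seed))
      add(paste0(scenario, "_summary.json"),
          function(p) export_summary_json(res, p))
      add(paste0(scenario, "_npv_cdf.csv"),
          function(p) export_cdf(res$npv_draws, p))
      add(paste0(scenario, "_streams.csv"),
          function(p) export_stream_table(res$streams, p, scenario))
      if (identical(flags$draws, "true"))
        add(paste0(scenario, "_draws.csv"), function(p)
          utils::write.csv(data.frame(tci = res$tci_draws,
                                      tpc = res$tpc_draws,
                                      npv = res$npv_draws),
                           p, row.names = FALSE))
    } else if (command == "tornado") {
      tab <- oat_tornado(scenario, params)
      add(paste0(scenario, "_tornado.csv"),
          function(p) utils::write.csv(tab, p, row.names = FALSE))
    } else if (command == "sweep-extraction") {
      sw <- extraction_sweep(scenario, params,
                             e_grid = parse_grid(flags$grid, 0:15))
      add(paste0(scenario, "_extraction_sweep.csv"),
          function(p) utils::write.csv(sw, p, row.names = FALSE))
    } else if (command == "sweep-scale") {
      sw <- scale_sweep(scenario, params,
        capacities = parse_grid(flags$grid,
                                c(1000, 2000, 5000, 10000, 20000, 50000,
                                  100000)))
      add(paste0(scenario, "_scale_sweep.csv"),
          function(p) utils::write.csv(sw, p, row.names = FALSE))
    } else if (command == "sweep-discount") {
      sw <- discount_rate_sweep(scenario, params,
        r_grid = parse_grid(flags$grid, seq(0.06, 0.12, by = 0.01)))
      add(paste0(scenario, "_discount_sweep.csv"),
          function(p) utils::write.csv(sw, p, row.names = FALSE))
    } else if (command == "supply") {
      region <- if (is.null(flags$region)) NULL
                else switch(flags$region,
                            livestock = region_livestock(),
                            arable = region_arable(),
                            stop(sprintf("unknown region '%s'", flags$region),
                                 call. = FALSE))
      res <- run_supply_simulation(region = region,
                                   n = if (is.null(n)) 1000 else n,
                                   seed = seed)
      add("supply_draws.csv", function(p)
        utils::write.csv(data.frame(draw = seq_len(res$n),
                                    radius_km = res$radius_draws,
                                    haul_km = res$haul_draws,
                                    cost_gbp_per_wet_t = res$draws),
                         p, row.names = FALSE))
      add("supply_summary.json", function(p)
        jsonlite::write_json(list(region = res$region, n = res$n,
                                  seed = res$seed, mean = res$mean,
                                  sd = res$sd, mean_dm95 = res$mean_dm95,
                                  sd_dm95 = res$sd_dm95),
                             p, auto_unbox = TRUE, digits = NA))
    } else {
      stop(sprintf("unknown command '%s'", command), call. = FALSE)
    }
    write_manifest(out_dir, command, flags$config, seed, files)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
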