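#' Load a TEA configuration file
#'
#' Reads a hierarchical YAML configuration describing the full parameter
#' set — financial parameters, design basis, yields, price book, cost
#' factors, equipment and operating items, and scenario definitions — and
#' returns a validated [tea_params()] object. Every validation failure names
#' the offending configuration path (e.g. `prices.protein_price`).
#'
#' @param path path to a YAML configuration file.
#' @return a `tea_params` parameter set.
#' @seealso [save_config()], [generate_fixture()]; a packaged reference
#'   fixture is available via
#'   `system.file("extdata", "fixture_config.yaml", package = "silagetea")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- function(x, key, where) {
    if (is.null(x[[key]]))
      stop(sprintf("missing key '%s.%s'", where, key), call. = FALSE)
    x[[key]]
  }
  for (top in c("financial", "basis", "yields", "prices", "factors",
                "equipment", "operating", "scenarios"))
    if (is.null(cfg[[top]]))
      stop(sprintf("missing key '%s'", top), call. = FALSE)

  fin <- cfg$financial
  financial <- financial_params(
    discount_rate = need(fin, "discount_rate", "financial"),
    lifetime = need(fin, "lifetime", "financial"),
    base_year = if (is.null(fin$base_year)) 2024 else fin$base_year,
    annualisation_method = if (is.null(fin$annualisation_method))
      "capital_recovery_factor" else fin$annualisation_method)

  basis <- do.call(design_basis, cfg$basis)
  yields <- do.call(yield_set, cfg$yields)

  prices <- lapply(names(cfg$prices), function(nm)
    dist_from_list(cfg$prices[[nm]], paste0("prices.", nm)))
  names(prices) <- names(cfg$prices)

  factors <- factor_set(direct = unlist(need(cfg$factors, "direct", "factors")),
                        indirect = need(cfg$factors, "indirect", "factors"))

  equipment <- lapply(cfg$equipment, function(it)
    equipment_item(need(it, "name", "equipment"),
                   need(it, "purchase_cost",
                        paste0("equipment.", it$name)),
                   unlist(need(it, "scenarios",
                               paste0("equipment.", it$name)))))

  operating <- lapply(cfg$operating, function(it)
    operating_item(need(it, "name", "operating"),
                   need(it, "category", paste0("operating.", it$name)),
                   need(it, "unit_price", paste0("operating.", it$name)),
                   need(it, "annual_usage", paste0("operating.", it$name)),
                   unlist(need(it, "scenarios",
                               paste0("operating.", it$name)))))

  scenarios <- lapply(names(cfg$scenarios), function(nm) {
    sc <- cfg$scenarios[[nm]]
    rs <- unlist(need(sc, "revenue_streams", paste0("scenarios.", nm)))
    scenario_definition(nm, rs, isTRUE(sc$includes_fermentation))
  })
  names(scenarios) <- names(cfg$scenarios)

  tea_params(financial, basis, yields, prices, factors,
             equipment, operating, scenarios)
}

params_to_list <- function(params) {
  list(
    financial = unclass(params$financial),
    basis = unclass(params$basis),
    yields = unclass(params$yields),
    prices = lapply(params$prices, dist_to_list),
    factors = list(direct = as.list(params$factors$direct),
                   indirect = params$factors$indirect),
    equipment = lapply(params$equipment, function(it)
      list(name = it$name, purchase_cost = dist_to_list(it$purchase_cost),
           scenarios = as.list(it$scenarios))),
    operating = lapply(params$operating, function(it)
      list(name = it$name, category = it$category,
           unit_price = dist_to_list(it$unit_price),
           annual_usage = it$annual_usage,
           scenarios = as.list(it$scenarios))),
    scenarios = lapply(params$scenarios, function(sc)
      list(revenue_streams = as.list(sc$revenue_streams),
           includes_fermentation = sc$includes_fermentation)))
}

#' Write a TEA parameter set to a configuration file
#'
#' Serialises a parameter set to YAML such that
#' `load_config(save_config(params, path))` reproduces the set (numbers are
#' written at 15 significant digits).
#'
#' @param params a `tea_params` parameter set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "tea_params"))
  writeLines(yaml::as.yaml(params_to_list(params), precision = 15), path)
  invisible(path)
}

#' Export a resolved parameter set as JSON
#'
#' @param params a `tea_params` parameter set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_params_json <- function(params, path) {
  stopifnot(inherits(params, "tea_params"))
  jsonlite::write_json(params_to_list(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
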