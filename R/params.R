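#' Assemble a full TEA parameter set
#'
#' Bundles everything a scenario evaluation needs: financial parameters,
#' design basis, extraction yield set, price book (protein, lipid-rich
#' biomass, residual solids, lignin, silage — all [dist_spec()]s in GBP/kg),
#' installation factor set, equipment and operating item lists, and the
#' scenario definitions. Validated on construction.
#'
#' @param financial a [financial_params()].
#' @param basis a [design_basis()].
#' @param yields a [yield_set()].
#' @param prices named list of [dist_spec()]s; must contain
#'   `protein_price`, `lipid_biomass_price`, `residual_solids_price`,
#'   `lignin_price`, `silage_price`.
#' @param factors a [factor_set()].
#' @param equipment list of [equipment_item()]s.
#' @param operating list of [operating_item()]s.
#' @param scenarios named list of [scenario_definition()]s.
#' @return object of class `tea_params`.
#' @export
tea_params <- function(financial, basis, yields, prices, factors,
                       equipment, operating,
                       scenarios = default_scenarios()) {
  params <- structure(list(financial = financial, basis = basis,
                           yields = yields, prices = prices,
                           factors = factors, equipment = equipment,
                           operating = operating, scenarios = scenarios),
                      class = "tea_params")
  problems <- validate_tea_params(params)
  if (length(problems))
    stop("invalid parameter set:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  params
}

required_prices <- c("protein_price", "lipid_biomass_price",
                     "residual_solids_price", "lignin_price", "silage_price")

#' Validate a TEA parameter set
#'
#' Checks class structure, required price-book entries, distribution
#' invariants (non-negative price and cost draws after truncation), scenario
#' cross-references (every revenue stream must point at a price-book entry;
#' every scenario must have at least one equipment and operating item), and
#' that scenario 2 is a superset of scenario 1's revenue streams.
#'
#' @param params a `tea_params` object.
#' @return character vector of problems; empty when valid.
#' @export
validate_tea_params <- function(params) {
  p <- character()
  chk <- function(cond, msg) if (!cond) p <<- c(p, msg)
  chk(inherits(params$financial, "financial_params"),
      "financial: not a financial_params object")
  chk(inherits(params$basis, "design_basis"),
      "basis: not a design_basis object")
  chk(inherits(params$yields, "yield_set"), "yields: not a yield_set object")
  chk(inherits(params$factors, "factor_set"),
      "factors: not a factor_set object")
  for (nm in required_prices)
    chk(is_dist_spec(params$prices[[nm]]),
        sprintf("prices.%s: missing or not a dist_spec", nm))
  for (nm in names(params$prices)) {
    d <- params$prices[[nm]]
    if (is_dist_spec(d) && d$kind != "normal" && dist_bounds(d)[1] < 0)
      p <- c(p, sprintf("prices.%s: draws can be negative after truncation",
                        nm))
  }
  for (it in params$equipment)
    chk(inherits(it, "equipment_item"),
        "equipment: entries must be equipment_item objects")
  for (it in params$operating)
    chk(inherits(it, "operating_item"),
        "operating: entries must be operating_item objects")
  for (sc in params$scenarios) {
    chk(inherits(sc, "scenario_definition"),
        "scenarios: entries must be scenario_definition objects")
    if (!inherits(sc, "scenario_definition")) next
    for (ref in sc$revenue_streams)
      chk(ref %in% names(params$prices),
          sprintf("scenarios.%s: revenue stream references unknown price '%s'",
                  sc$name, ref))
    chk(length(scenario_equipment(params, sc$name)) > 0,
        sprintf("scenarios.%s: no equipment items", sc$name))
    chk(length(scenario_operating(params, sc$name)) > 0,
        sprintf("scenarios.%s: no operating items", sc$name))
  }
  s1 <- params$scenarios$scenario1
  s2 <- params$scenarios$scenario2
  if (inherits(s1, "scenario_definition") &&
      inherits(s2, "scenario_definition"))
    chk(all(names(s1$revenue_streams) %in% names(s2$revenue_streams)),
        "scenarios: scenario2 must include every scenario1 revenue stream")
  p
}

#' @export
print.tea_params <- function(x, ...) {
  cat("<tea_params>\n")
  cat(sprintf("  %d equipment items, %d operating items, %d scenarios\n",
              length(x$equipment), length(x$operating), length(x$scenarios)))
  cat(sprintf("  discount rate %.0f%%, lifetime %d y, base year %s\n",
              100 * x$financial$discount_rate, x$financial$lifetime,
              x$financial$base_year))
  cat(sprintf("  silage capacity %s t/y, extraction efficiency %g g/100 g\n",
              format(x$basis$silage_capacity, big.mark = ","),
              x$basis$protein_extraction_efficiency))
  invisible(x)
}
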