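#' Equipment item
#'
#' A purchasable equipment item with an uncertain purchase cost and the set
#' of scenarios it belongs to. Anaerobic-digestion infrastructure is never an
#' item: residual solids are valorised through external facilities and AD
#' capital is excluded from TCI.
#'
#' @param name item name.
#' @param purchase_cost a [dist_spec()] in GBP; draws must be non-negative,
#'   which truncation limits guarantee for uncertain items.
#' @param scenarios character vector of scenario names the item belongs to.
#' @return object of class `equipment_item`.
#' @export
equipment_item <- function(name, purchase_cost,
                           scenarios = c("scenario1", "scenario2")) {
  purchase_cost <- dist_from_list(purchase_cost, paste0("equipment.", name))
  if (dist_bounds(purchase_cost)[1] < 0)
    stop(sprintf("equipment.%s: purchase cost can go negative; truncate",
                 name), call. = FALSE)
  structure(list(name = name, purchase_cost = purchase_cost,
                 scenarios = scenarios),
            class = "equipment_item")
}

#' Operating cost item
#'
#' An annual operating item: `annual_usage` units per year at an uncertain
#' `unit_price`. Lump-sum items (labour, maintenance, fixed charges,
#' membrane replacement) use `annual_usage = 1` with the price carrying the
#' full GBP/y amount. Membrane replacement is a recurring operating item,
#' not periodic capital.
#'
#' @param name item name.
#' @param category one of `"raw_material"`, `"utility"`, `"labour"`,
#'   `"maintenance"`, `"membrane_replacement"`, `"fixed"`.
#' @param unit_price a [dist_spec()], GBP per unit.
#' @param annual_usage units consumed per year (>= 0).
#' @param scenarios scenario membership.
#' @return object of class `operating_item`.
#' @export
operating_item <- function(name, category, unit_price, annual_usage = 1,
                           scenarios = c("scenario1", "scenario2")) {
  category <- match.arg(category,
    c("raw_material", "utility", "labour", "maintenance",
      "membrane_replacement", "fixed"))
  unit_price <- dist_from_list(unit_price, paste0("operating.", name))
  if (annual_usage < 0) stop("annual_usage must be >= 0", call. = FALSE)
  if (dist_bounds(unit_price)[1] < 0)
    stop(sprintf("operating.%s: unit price can go negative; truncate", name),
         call. = FALSE)
  structure(list(name = name, category = category, unit_price = unit_price,
                 annual_usage = as.numeric(annual_usage),
                 scenarios = scenarios),
            class = "operating_item")
}

#' Installation factor set
#'
#' Factors of a Garrett-style factored capital estimate: named direct-cost
#' multipliers (piping, electrical, foundations, utilities, installation)
#' applied additively to the purchased-equipment cost, then a single
#' multiplicative indirect factor (engineering and contingency).
#'
#' @param direct named numeric vector of direct factors (each >= 0).
#' @param indirect indirect factor (>= 0).
#' @return object of class `factor_set`.
#' @export
factor_set <- function(direct = c(piping = 0.45, electrical = 0.20,
                                  foundations = 0.15, utilities = 0.25,
                                  installation = 0.45),
                       indirect = 0.25) {
  direct <- unlist(direct)
  if (is.null(names(direct)) || any(names(direct) == ""))
    stop("direct factors must be named", call. = FALSE)
  if (any(direct < 0) || indirect < 0)
    stop("all factors must be >= 0", call. = FALSE)
  structure(list(direct = direct, indirect = indirect), class = "factor_set")
}

#' Total capital investment by factored costing
#'
#' `TCI = [sum_i cost_i * (1 + sum(direct factors))] * (1 + indirect)`.
#' The per-item breakdown retains installed costs (purchase cost times the
#' full multiplier), so the breakdown sums exactly to the total.
#'
#' @param equipment_costs named numeric vector of sampled purchase costs,
#'   GBP (one value per equipment item in the scenario).
#' @param factors a [factor_set()].
#' @return list of class `capital_estimate` with `total` (GBP) and
#'   `breakdown` (named vector of installed costs).
#' @examples
#' total_capital_investment(c(extruder = 1e6),
#'   factor_set(c(piping = 1.5), indirect = 0.2))$total  # 3e6
#' @export
total_capital_investment <- function(equipment_costs, factors) {
  stopifnot(inherits(factors, "factor_set"))
  if (length(equipment_costs) == 0)
    stop("empty equipment list", call. = FALSE)
  if (any(equipment_costs < 0))
    stop("negative sampled equipment cost", call. = FALSE)
  mult <- (1 + sum(factors$direct)) * (1 + factors$indirect)
  breakdown <- equipment_costs * mult
  structure(list(total = sum(breakdown), breakdown = breakdown),
            class = "capital_estimate")
}

#' Total production cost from sampled operating items
#'
#' `TPC = sum usage * unit_price`, aggregated per category; lump-sum fixed
#' items enter through usage 1. The per-category breakdown sums exactly to
#' the total.
#'
#' @param items list of `operating_item`s in the scenario.
#' @param unit_prices named numeric vector of sampled unit prices, one per
#'   item (names matching item names).
#' @return list of class `operating_estimate` with `total` (GBP/y),
#'   `by_category` and `by_item` breakdowns.
#' @export
total_production_cost <- function(items, unit_prices) {
  if (length(items) == 0) stop("empty operating-item list", call. = FALSE)
  nm <- vapply(items, `[[`, "", "name")
  if (!all(nm %in% names(unit_prices)))
    stop("missing sampled price for: ",
         paste(setdiff(nm, names(unit_prices)), collapse = ", "),
         call. = FALSE)
  usage <- vapply(items, `[[`, 0, "annual_usage")
  cat_ <- vapply(items, `[[`, "", "category")
  cost <- usage * unit_prices[nm]
  names(cost) <- nm
  structure(list(total = sum(cost),
                 by_category = tapply(cost, cat_, sum),
                 by_item = cost),
            class = "operating_estimate")
}

#' Capital recovery factor
#'
#' `CRF(r, T) = r (1+r)^T / ((1+r)^T - 1)`, the annuity factor converting a
#' present capital sum into an equivalent constant annual charge over `T`
#' years at discount rate `r`.
#'
#' @param r discount rate, fraction per year.
#' @param lifetime plant lifetime, years.
#' @return the factor (1/y).
#' @export
capital_recovery_factor <- function(r, lifetime) {
  stopifnot(lifetime >= 1)
  if (r == 0) return(1 / lifetime)
  g <- (1 + r)^lifetime
  r * g / (g - 1)
}

#' Annualise a capital investment
#'
#' Converts TCI into an annual capital charge, either by the capital
#' recovery factor (default) or by straight-line division over the lifetime.
#' At `r = 0` the CRF method reduces to straight line.
#'
#' @param tci total capital investment, GBP (>= 0).
#' @param fin a [financial_params()].
#' @return annual charge, GBP/y.
#' @examples
#' annualise_capital(4.8e6, financial_params())  # ~449,660 GBP/y
#' @export
annualise_capital <- function(tci, fin) {
  stopifnot(inherits(fin, "financial_params"), tci >= 0)
  if (fin$annualisation_method == "straight_line")
    return(tci / fin$lifetime)
  tci * capital_recovery_factor(fin$discount_rate, fin$lifetime)
}
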