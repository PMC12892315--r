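#' Financial parameters
#'
#' Discounting and annualisation settings for the discounted-cash-flow
#' valuation: an 8% discount rate over a 25-year operational life with 2024
#' as the base year, no salvage value, and capital-recovery-factor
#' annualisation by default.
#'
#' @param discount_rate fraction per year, in (0, 1).
#' @param lifetime plant operational life, whole years (>= 1).
#' @param base_year calendar base year for the cost basis.
#' @param annualisation_method `"capital_recovery_factor"` or
#'   `"straight_line"`.
#' @return object of class `financial_params`.
#' @export
financial_params <- function(discount_rate = 0.08, lifetime = 25,
                             base_year = 2024,
                             annualisation_method = "capital_recovery_factor") {
  annualisation_method <- match.arg(annualisation_method,
    c("capital_recovery_factor", "straight_line"))
  if (!is.numeric(discount_rate) || discount_rate <= 0 || discount_rate >= 1)
    stop("discount_rate must lie in (0, 1)", call. = FALSE)
  if (lifetime < 1 || lifetime != round(lifetime))
    stop("lifetime must be a whole number of years >= 1", call. = FALSE)
  structure(list(discount_rate = as.numeric(discount_rate),
                 lifetime = as.integer(lifetime),
                 base_year = as.numeric(base_year),
                 annualisation_method = annualisation_method),
            class = "financial_params")
}

#' Scenario definition
#'
#' Names the revenue streams of a biorefinery configuration and whether the
#' lipid fermentation stage is included. Scenario 1 sells protein
#' concentrate, lignin and AD solids; scenario 2 adds the lipid-rich yeast
#' stream. Neither scenario carries AD capital.
#'
#' @param name scenario name.
#' @param revenue_streams named character vector mapping stream id to a
#'   price-book entry (prices are GBP/kg; stream masses are t/y).
#' @param includes_fermentation logical flag.
#' @return object of class `scenario_definition`.
#' @export
scenario_definition <- function(name, revenue_streams, includes_fermentation) {
  stopifnot(is.character(revenue_streams), !is.null(names(revenue_streams)))
  structure(list(name = name, revenue_streams = revenue_streams,
                 includes_fermentation = isTRUE(includes_fermentation)),
            class = "scenario_definition")
}

default_scenarios <- function() {
  s1 <- c(protein_product = "protein_price",
          lignin = "lignin_price",
          ad_solids = "residual_solids_price")
  list(
    scenario1 = scenario_definition("scenario1", s1, FALSE),
    scenario2 = scenario_definition("scenario2",
      c(s1, lipid_rich_yeast = "lipid_biomass_price"), TRUE))
}

resolve_scenario <- function(params, scenario) {
  if (inherits(scenario, "scenario_definition")) return(scenario)
  sc <- params$scenarios[[scenario]]
  if (is.null(sc)) stop(sprintf("unknown scenario '%s'", scenario),
                        call. = FALSE)
  sc
}

scenario_equipment <- function(params, scenario_name) {
  Filter(function(it) scenario_name %in% it$scenarios, params$equipment)
}

scenario_operating <- function(params, scenario_name) {
  Filter(function(it) scenario_name %in% it$scenarios, params$operating)
}

#' Monte Carlo configuration
#'
#' @param n_draws number of Monte Carlo draws (default 10,000).
#' @param seed RNG seed; identical (seed, n, params) give identical results.
#' @param truncation_policy truncated-normal policy, see [sample_dist()].
#' @return object of class `mc_config`.
#' @export
mc_config <- function(n_draws = 10000, seed = 1,
                      truncation_policy = c("resample", "clip")) {
  stopifnot(n_draws >= 1)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 truncation_policy = match.arg(truncation_policy)),
            class = "mc_config")
}

# evaluate code under a local seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# present value of a 1 GBP/y annuity over years 1..T
annuity_factor <- function(r, lifetime) {
  if (r == 0) return(lifetime)
  (1 - (1 + r)^(-lifetime)) / r
}

#' Annual cashflow series
#'
#' @param revenues,costs numeric vectors of annual revenues and costs,
#'   GBP/y, one entry per operating year 1..T.
#' @return object of class `cashflow_series`.
#' @export
cashflow_series <- function(revenues, costs) {
  stopifnot(length(revenues) == length(costs), length(revenues) >= 1,
            all(is.finite(revenues)), all(is.finite(costs)))
  structure(list(revenues = revenues, costs = costs),
            class = "cashflow_series")
}

#' Net present value
#'
#' `NPV = sum_t (R_t - C_t) / (1+r)^t - TCI`, summed term by term over the
#' operating years, with the capital spent at time zero.
#'
#' @param cash a [cashflow_series()].
#' @param r discount rate, must be > -1.
#' @param tci total capital investment, GBP.
#' @return NPV in GBP.
#' @examples
#' npv(cashflow_series(rep(10e6, 25), rep(0, 25)), 0.08, 50e6)  # ~56.75e6
#' @export
npv <- function(cash, r, tci) {
  stopifnot(inherits(cash, "cashflow_series"))
  if (r <= -1) stop("discount rate must exceed -1", call. = FALSE)
  t <- seq_along(cash$revenues)
  sum((cash$revenues - cash$costs) / (1 + r)^t) - tci
}

#' Unit production cost of protein
#'
#' `(annualised TCI + TPC) / annual protein output`, in GBP per kg.
#'
#' @param tci total capital investment, GBP.
#' @param tpc total production cost, GBP/y.
#' @param protein_output annual protein output, t/y (> 0).
#' @param fin a [financial_params()].
#' @return GBP/kg protein.
#' @examples
#' unit_cost(4.8e6, 14e6, 5000, financial_params())  # ~2.89 GBP/kg
#' @export
unit_cost <- function(tci, tpc, protein_output, fin) {
  if (protein_output <= 0)
    stop("protein_output must be > 0", call. = FALSE)
  (annualise_capital(tci, fin) + tpc) / (protein_output * 1000)
}

#' Summarise a vector of Monte Carlo draws
#'
#' Median, 90% confidence interval (5th and 95th percentiles under the
#' linear-interpolation quantile convention, `stats::quantile` type 7),
#' mean and standard deviation.
#'
#' @param draws numeric vector, length >= 1.
#' @return list with `median`, `ci90_low`, `ci90_high`, `mean`, `sd`.
#' @export
summarize_draws <- function(draws) {
  if (length(draws) == 0) stop("empty draw vector", call. = FALSE)
  q <- stats::quantile(draws, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  list(median = q[2], ci90_low = q[1], ci90_high = q[3],
       mean = mean(draws),
       sd = if (length(draws) > 1) stats::sd(draws) else 0)
}

# median values of every uncertain input, with optional overrides:
# overrides = list(prices =, equipment =, operating = named numerics,
#                  discount_rate =, basis = named list)
point_values <- function(params, scenario_name, overrides = list()) {
  sc_eq <- scenario_equipment(params, scenario_name)
  sc_op <- scenario_operating(params, scenario_name)
  eq <- vapply(sc_eq, function(it) dist_median(it$purchase_cost), 0)
  names(eq) <- vapply(sc_eq, `[[`, "", "name")
  op <- vapply(sc_op, function(it) dist_median(it$unit_price), 0)
  names(op) <- vapply(sc_op, `[[`, "", "name")
  pr <- vapply(params$prices, dist_median, 0)
  ov <- function(x, o) { if (length(o)) x[names(o)] <- unlist(o); x }
  list(equipment = ov(eq, overrides$equipment),
       operating = ov(op, overrides$operating),
       prices = ov(pr, overrides$prices),
       discount_rate = if (!is.null(overrides$discount_rate))
         overrides$discount_rate else params$financial$discount_rate)
}

stream_revenue <- function(streams, revenue_streams, prices,
                           zero_coproducts = FALSE) {
  total <- 0
  for (stream in names(revenue_streams)) {
    if (zero_coproducts && stream != "protein_product") next
    ref <- revenue_streams[[stream]]
    total <- total + stream_mass(streams, stream) * 1000 * prices[[ref]]
  }
  total
}

#' Deterministic scenario evaluation at central values
#'
#' Evaluates TCI, TPC, annual revenue and NPV with every uncertain
#' parameter fixed at its distribution median, optionally overriding
#' individual values (the workhorse of one-at-a-time sensitivity).
#'
#' @param scenario scenario name or definition.
#' @param params a `tea_params` parameter set.
#' @param basis a [design_basis()]; defaults to the one in `params`.
#' @param overrides optional list with named-numeric elements `prices`,
#'   `equipment`, `operating`, scalar `discount_rate`, and list `basis`.
#' @param zero_coproducts if TRUE only the protein stream earns revenue.
#' @return list with `tci`, `tpc`, `revenue`, `npv`, `streams`.
#' @export
evaluate_point <- function(scenario, params, basis = params$basis,
                           overrides = list(), zero_coproducts = FALSE) {
  sc <- resolve_scenario(params, scenario)
  if (length(overrides$basis)) {
    b <- unclass(basis)
    b[names(overrides$basis)] <- overrides$basis
    basis <- do.call(design_basis, b)
  }
  vals <- point_values(params, sc$name, overrides)
  tci <- total_capital_investment(vals$equipment, params$factors)$total
  tpc <- total_production_cost(scenario_operating(params, sc$name),
                               vals$operating)$total
  streams <- product_rates(basis, sc)
  revenue <- stream_revenue(streams, sc$revenue_streams, vals$prices,
                            zero_coproducts)
  fin <- params$financial
  af <- annuity_factor(vals$discount_rate, fin$lifetime)
  list(tci = tci, tpc = tpc, revenue = revenue,
       npv = (revenue - tpc) * af - tci, streams = streams)
}

#' Monte Carlo simulation of a scenario
#'
#' For each draw, samples every uncertain parameter independently (equipment
#' purchase costs, operating unit prices, product prices), evaluates TCI by
#' factored costing, TPC, annual revenue (stream masses times sampled
#' prices, constant over the plant life), and NPV at the configured discount
#' rate with TCI spent at time zero. Returns the full draw vectors, their
#' summaries, the expected NPV (arithmetic mean of the draws) and the
#' probability of a positive NPV.
#'
#' @param scenario scenario name or definition.
#' @param params a `tea_params` parameter set.
#' @param basis a [design_basis()]; defaults to the one in `params`.
#' @param mc an [mc_config()].
#' @return object of class `scenario_result`.
#' @export
simulate_scenario <- function(scenario, params, basis = params$basis,
                              mc = mc_config()) {
  sc <- resolve_scenario(params, scenario)
  sc_eq <- scenario_equipment(params, sc$name)
  sc_op <- scenario_operating(params, sc$name)
  if (length(sc_eq) == 0) stop("scenario has no equipment items",
                               call. = FALSE)
  n <- mc$n_draws
  pol <- mc$truncation_policy
  draws <- with_local_seed(mc$seed, {
    eq <- vapply(sc_eq, function(it)
      sample_dist(it$purchase_cost, n, pol), numeric(n))
    op <- vapply(sc_op, function(it)
      sample_dist(it$unit_price, n, pol), numeric(n))
    pr <- vapply(params$prices, function(d)
      sample_dist(d, n, pol), numeric(n))
    list(eq = matrix(eq, nrow = n), op = matrix(op, nrow = n),
         pr = matrix(pr, nrow = n,
                     dimnames = list(NULL, names(params$prices))))
  })
  # elementwise products summed left-to-right, matching the order of the
  # deterministic breakdown sums so degenerate draws reproduce them exactly
  mult <- (1 + sum(params$factors$direct)) * (1 + params$factors$indirect)
  tci <- rowSums(draws$eq * mult)
  usage <- vapply(sc_op, `[[`, 0, "annual_usage")
  tpc <- rowSums(draws$op * rep(usage, each = n))
  streams <- product_rates(basis, sc)
  revenue <- numeric(n)
  for (stream in names(sc$revenue_streams)) {
    ref <- sc$revenue_streams[[stream]]
    revenue <- revenue + stream_mass(streams, stream) * 1000 * draws$pr[, ref]
  }
  fin <- params$financial
  af <- annuity_factor(fin$discount_rate, fin$lifetime)
  npv_draws <- (revenue - tpc) * af - tci
  structure(list(
    scenario = sc$name, n = n, seed = mc$seed,
    tci_draws = tci, tpc_draws = tpc, npv_draws = npv_draws,
    revenue_draws = revenue, streams = streams,
    summaries = list(tci = summarize_draws(tci), tpc = summarize_draws(tpc),
                     npv = summarize_draws(npv_draws)),
    enpv = mean(npv_draws),
    p_npv_positive = mean(npv_draws > 0)),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  fm <- function(v) sprintf("%.1f", v / 1e6)
  cat(sprintf("<scenario_result> %s (n = %s, seed = %d)\n",
              x$scenario, format(x$n, big.mark = ","), x$seed))
  for (q in c("tci", "tpc", "npv")) {
    s <- x$summaries[[q]]
    cat(sprintf("  %s: median GBP %sM (90%% CI %sM to %sM)\n",
                toupper(q), fm(s$median), fm(s$ci90_low), fm(s$ci90_high)))
  }
  cat(sprintf("  ENPV: GBP %sM; P(NPV > 0) = %.3f\n",
              fm(x$enpv), x$p_npv_positive))
  invisible(x)
}
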