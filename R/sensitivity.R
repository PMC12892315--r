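#' Declare a one-at-a-time sensitivity parameter
#'
#' Identifies a model input by name — a price-book entry, an operating or
#' equipment item, a design-basis field, or `"discount_rate"` — together
#' with the low/high bounds over which it is varied while every other input
#' is held at its distribution median.
#'
#' @param name parameter name.
#' @param low,high evaluation bounds (low <= high).
#' @return object of class `tea_parameter`.
#' @export
tea_parameter <- function(name, low, high) {
  if (is.null(low) || is.null(high) || !is.finite(low) || !is.finite(high))
    stop(sprintf("parameter '%s' needs finite low/high bounds", name),
         call. = FALSE)
  if (low > high) stop(sprintf("parameter '%s': low > high", name),
                       call. = FALSE)
  structure(list(name = name, low = low, high = high),
            class = "tea_parameter")
}

param_override <- function(params, name, value) {
  if (name == "discount_rate") return(list(discount_rate = value))
  if (name %in% names(params$prices)) {
    ov <- list(); ov$prices <- stats::setNames(value, name); return(ov)
  }
  if (name %in% vapply(params$operating, `[[`, "", "name"))
    return(list(operating = stats::setNames(value, name)))
  if (name %in% vapply(params$equipment, `[[`, "", "name"))
    return(list(equipment = stats::setNames(value, name)))
  if (name %in% names(unclass(params$basis)))
    return(list(basis = stats::setNames(list(value), name)))
  stop(sprintf("unknown sensitivity parameter '%s'", name), call. = FALSE)
}

# replace the named parameter's distribution by a point value (MC mode)
set_parameter <- function(params, name, value) {
  if (name == "discount_rate") {
    params$financial$discount_rate <- value
    return(params)
  }
  if (name %in% names(params$prices)) {
    params$prices[[name]] <- dist_point(value)
    return(params)
  }
  for (i in seq_along(params$operating))
    if (params$operating[[i]]$name == name) {
      params$operating[[i]]$unit_price <- dist_point(value)
      return(params)
    }
  for (i in seq_along(params$equipment))
    if (params$equipment[[i]]$name == name) {
      params$equipment[[i]]$purchase_cost <- dist_point(value)
      return(params)
    }
  stop(sprintf("unknown sensitivity parameter '%s'", name), call. = FALSE)
}

#' Default one-at-a-time parameter list
#'
#' The scenario's product prices (over their truncation bounds, or the
#' central 95% interval for untruncated normals), the silage feedstock and
#' electricity operating prices, and the discount rate over 6-12%.
#'
#' @param params a `tea_params` parameter set.
#' @param scenario scenario name.
#' @return list of [tea_parameter()]s.
#' @export
default_oat_parameters <- function(params, scenario = "scenario1") {
  sc <- resolve_scenario(params, scenario)
  out <- list()
  for (ref in unique(sc$revenue_streams)) {
    b <- dist_bounds(params$prices[[ref]])
    out[[ref]] <- tea_parameter(ref, b[1], b[2])
  }
  for (nm in c("silage_feedstock", "electricity")) {
    it <- Filter(function(i) i$name == nm,
                 scenario_operating(params, sc$name))
    if (length(it)) {
      b <- dist_bounds(it[[1]]$unit_price)
      out[[nm]] <- tea_parameter(nm, b[1], b[2])
    }
  }
  out$discount_rate <- tea_parameter("discount_rate", 0.06, 0.12)
  out
}

#' One-at-a-time tornado analysis
#'
#' Varies each listed parameter between its low and high bound while all
#' other inputs are held at their distribution medians, records the ENPV at
#' both bounds and the absolute swing, and returns the entries sorted by
#' swing (largest first). By default the evaluation at each bound is
#' deterministic, so the ENPV of the degenerate evaluation is its NPV; with
#' `method = "mc"` a full Monte Carlo run is performed per bound with the
#' parameter pinned, and the mean NPV reported.
#'
#' @param scenario scenario name or definition.
#' @param params a `tea_params` parameter set.
#' @param basis a [design_basis()].
#' @param parameters list of [tea_parameter()]s.
#' @param method `"deterministic"` (default) or `"mc"`.
#' @param mc an [mc_config()], used when `method = "mc"`.
#' @return data frame of class `tornado_table` with columns `parameter`,
#'   `low`, `high`, `enpv_at_low`, `enpv_at_high`, `swing`.
#' @export
oat_tornado <- function(scenario, params, basis = params$basis,
                        parameters = default_oat_parameters(params, scenario),
                        method = c("deterministic", "mc"),
                        mc = mc_config()) {
  method <- match.arg(method)
  sc <- resolve_scenario(params, scenario)
  enpv_at <- function(p, value) {
    if (method == "deterministic")
      evaluate_point(sc, params, basis,
                     overrides = param_override(params, p$name, value))$npv
    else
      simulate_scenario(sc, set_parameter(params, p$name, value), basis,
                        mc)$enpv
  }
  rows <- lapply(parameters, function(p) {
    lo <- enpv_at(p, p$low); hi <- enpv_at(p, p$high)
    data.frame(parameter = p$name, low = p$low, high = p$high,
               enpv_at_low = lo, enpv_at_high = hi, swing = abs(hi - lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_table", "data.frame")
  out
}

sweep_result <- function(df, lever) {
  rownames(df) <- NULL
  structure(df, lever = lever, class = c("sweep_result", "data.frame"))
}

#' Extraction-efficiency sweep
#'
#' Evaluates ENPV across a grid of protein extraction efficiencies
#' (g protein per 100 g silage), recomputing the protein stream at each
#' point with all uncertain inputs at their medians. In
#' `revenue_mode = "protein_only"` the coproduct revenues (lignin, AD
#' solids, lipid-rich yeast) are zeroed, isolating the protein stream's
#' contribution.
#'
#' @param scenario scenario name or definition.
#' @param params a `tea_params` parameter set.
#' @param basis a [design_basis()].
#' @param e_grid strictly increasing efficiency grid within [0, 100].
#' @param revenue_mode `"multiproduct"` or `"protein_only"`.
#' @return `sweep_result` data frame with columns `efficiency`, `enpv`,
#'   `unit_cost` (NA where protein output is zero).
#' @export
extraction_sweep <- function(scenario, params, basis = params$basis,
                             e_grid = 0:15,
                             revenue_mode = c("multiproduct",
                                              "protein_only")) {
  revenue_mode <- match.arg(revenue_mode)
  stopifnot(all(diff(e_grid) > 0), all(e_grid >= 0), all(e_grid <= 100))
  sc <- resolve_scenario(params, scenario)
  fin <- params$financial
  rows <- lapply(e_grid, function(e) {
    ev <- evaluate_point(sc, params, basis,
      overrides = list(basis = list(protein_extraction_efficiency = e)),
      zero_coproducts = revenue_mode == "protein_only")
    q <- stream_mass(ev$streams, "protein_product")
    data.frame(efficiency = e, enpv = ev$npv,
               unit_cost = if (q > 0) unit_cost(ev$tci, ev$tpc, q, fin)
                           else NA_real_)
  })
  sweep_result(do.call(rbind, rows), "protein_extraction_efficiency")
}

#' Marginal ENPV gain per unit of extraction efficiency
#'
#' Converts ENPV changes over contiguous extraction-efficiency bands into
#' marginal gains (GBP million per g protein/100 g silage), rounded to one
#' decimal, together with their unweighted mean and the sample standard
#' deviation across bands.
#'
#' @param enpv_by_range data frame with columns `range_low`, `range_high`
#'   (g/100 g) and `enpv_change` (GBP million).
#' @return list with `rows` (the input plus `marginal_gain`), `average` and
#'   `sd`.
#' @examples
#' marginal_gains(data.frame(range_low = 0, range_high = 3,
#'                           enpv_change = 125))$rows$marginal_gain  # 41.7
#' @export
marginal_gains <- function(enpv_by_range) {
  df <- as.data.frame(enpv_by_range)
  stopifnot(all(c("range_low", "range_high", "enpv_change") %in% names(df)))
  width <- df$range_high - df$range_low
  if (any(width <= 0)) stop("zero-width extraction range", call. = FALSE)
  if (nrow(df) > 1 && any(df$range_low[-1] != df$range_high[-nrow(df)]))
    stop("extraction ranges must be contiguous", call. = FALSE)
  df$marginal_gain <- round(df$enpv_change / width, 1)
  list(rows = df,
       average = mean(df$marginal_gain),
       sd = if (nrow(df) > 1) stats::sd(df$marginal_gain) else 0)
}

#' Reference ENPV changes per extraction-efficiency band
#'
#' The ENPV changes (GBP million) per extraction-efficiency band reported
#' for the two scenario configurations, used as the input to
#' [marginal_gains()] when benchmarking the roughly GBP 40-50 million gain
#' per additional g protein/100 g silage.
#'
#' @return data frame with columns `range_low`, `range_high`, `scenario1`,
#'   `scenario2`.
#' @export
enpv_change_table <- function() data.frame(
  range_low  = c(0, 3, 6, 10, 12),
  range_high = c(3, 6, 10, 12, 15),
  scenario1  = c(125, 125, 150, 100, 130),
  scenario2  = c(120, 150, 150, 100, 110))

bisect_root <- function(f, lo, hi, rel_tol = 1e-8, max_iter = 200) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi))
    stop("no sign change on the search bracket", call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) <= rel_tol * max(1, abs(mid)))
      return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Break-even protein selling price
#'
#' The protein price at which the deterministic NPV (all other inputs at
#' their medians) equals zero, found by bisection to a relative tolerance of
#' 1e-8. With coproduct revenues excluded and capital-recovery-factor
#' annualisation this equals [unit_cost()] analytically.
#'
#' @param scenario scenario name or definition.
#' @param params a `tea_params` parameter set.
#' @param basis a [design_basis()].
#' @param include_coproducts include coproduct revenues (default TRUE);
#'   coproducts strictly lower the break-even price.
#' @return break-even price, GBP/kg.
#' @export
breakeven_price <- function(scenario, params, basis = params$basis,
                            include_coproducts = TRUE) {
  sc <- resolve_scenario(params, scenario)
  q <- stream_mass(product_rates(basis, sc), "protein_product")
  if (q <= 0) stop("protein output must be > 0", call. = FALSE)
  f <- function(p) evaluate_point(sc, params, basis,
    overrides = list(prices = c(protein_price = p)),
    zero_coproducts = !include_coproducts)$npv
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  bisect_root(f, 0, hi, rel_tol = 1e-8)
}

#' Plant-scale sweep
#'
#' Evaluates economic performance across protein production capacities.
#' At each capacity the design basis is rescaled, capital scales with the
#' capacity ratio raised to `capital_exponent` (default 0.6, the classic
#' six-tenths rule), raw-material, utility and membrane-replacement
#' operating items scale linearly, and labour, maintenance and fixed items
#' scale with the capital exponent. ENPV (deterministic, at medians), the
#' break-even protein price and the unit production cost are reported at
#' each scale.
#'
#' @param scenario scenario name or definition.
#' @param params a `tea_params` parameter set.
#' @param capacities strictly increasing protein capacities, t/y.
#' @param capital_exponent capital scaling exponent, in (0, 1].
#' @return `sweep_result` data frame with columns `capacity`, `enpv`,
#'   `breakeven_price`, `unit_cost`.
#' @export
scale_sweep <- function(scenario, params,
                        capacities = c(1000, 2000, 5000, 10000, 20000,
                                       50000, 100000),
                        capital_exponent = 0.6) {
  stopifnot(capital_exponent > 0, capital_exponent <= 1,
            all(capacities > 0), all(diff(capacities) > 0))
  sc <- resolve_scenario(params, scenario)
  fin <- params$financial
  base <- evaluate_point(sc, params)
  q_base <- stream_mass(base$streams, "protein_product")
  vals <- point_values(params, sc$name)
  items <- scenario_operating(params, sc$name)
  variable <- c("raw_material", "utility", "membrane_replacement")
  item_cost <- vapply(items, function(it)
    it$annual_usage * vals$operating[[it$name]], 0)
  is_var <- vapply(items, `[[`, "", "category") %in% variable
  af <- annuity_factor(fin$discount_rate, fin$lifetime)
  rows <- lapply(capacities, function(S) {
    ratio <- S / q_base
    b <- scale_design(params$basis, S)
    tci <- base$tci * ratio^capital_exponent
    tpc <- sum(item_cost[is_var]) * ratio +
      sum(item_cost[!is_var]) * ratio^capital_exponent
    streams <- product_rates(b, sc)
    rev <- function(p) {
      pr <- vals$prices; pr[["protein_price"]] <- p
      stream_revenue(streams, sc$revenue_streams, pr)
    }
    p0 <- vals$prices[["protein_price"]]
    enpv <- (rev(p0) - tpc) * af - tci
    be <- bisect_root(function(p) (rev(p) - tpc) * af - tci,
                      0, 10 * max(1, p0), rel_tol = 1e-8)
    data.frame(capacity = S, enpv = enpv, breakeven_price = be,
               unit_cost = unit_cost(tci, tpc, S, fin))
  })
  sweep_result(do.call(rbind, rows), "protein_capacity")
}

#' Discount-rate sweep
#'
#' ENPV (deterministic, at medians) across a grid of discount rates,
#' typically 6-12%, isolating the cost-of-capital lever.
#'
#' @param scenario scenario name or definition.
#' @param params a `tea_params` parameter set.
#' @param basis a [design_basis()].
#' @param r_grid strictly increasing discount rates within (0, 1).
#' @return `sweep_result` data frame with columns `discount_rate`, `enpv`.
#' @export
discount_rate_sweep <- function(scenario, params, basis = params$basis,
                                r_grid = seq(0.06, 0.12, by = 0.01)) {
  stopifnot(all(r_grid > 0), all(r_grid < 1),
            length(r_grid) == 1 || all(diff(r_grid) > 0))
  sc <- resolve_scenario(params, scenario)
  enpv <- vapply(r_grid, function(r)
    evaluate_point(sc, params, basis,
                   overrides = list(discount_rate = r))$npv, 0)
  sweep_result(data.frame(discount_rate = r_grid, enpv = enpv),
               "discount_rate")
}
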