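#' Declare an uncertain parameter
#'
#' A `dist_spec` is the declarative description of an uncertain (or fixed)
#' parameter used everywhere uncertainty enters the model: equipment purchase
#' costs, operating unit prices, product prices and catchment parameters.
#' Four kinds are supported: a degenerate `point` value, an untruncated
#' `normal`, a `truncated_normal` (the workhorse for cost parameters, where
#' truncation limits keep draws physical), and a `uniform` on a bounded range
#' (the least-informative choice when only a range is known).
#'
#' @param kind one of `"point"`, `"normal"`, `"truncated_normal"`, `"uniform"`.
#' @param mean central value in the units of the parameter. For `uniform` it
#'   defaults to the midpoint of `[lower, upper]` and must equal it.
#' @param sd standard deviation of the underlying normal; must be 0 for
#'   `point` and strictly positive for `normal` and `truncated_normal`.
#' @param lower,upper truncation limits. Required (finite, `lower < upper`)
#'   for `truncated_normal` and `uniform`.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_normal(15, sd_from_ci(5, 0.95))     # protein price, GBP/kg
#' dist_truncnorm(3, 0.75, 2, 5)            # lipid-rich biomass, GBP/kg
#' dist_uniform(0.06, 0.10)                 # residual solids, GBP/kg
#' @export
dist_spec <- function(kind, mean = NULL, sd = 0, lower = -Inf, upper = Inf) {
  kind <- match.arg(kind, c("point", "normal", "truncated_normal", "uniform"))
  if (kind == "uniform") {
    if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
      stop("uniform requires finite lower < upper", call. = FALSE)
    mid <- (lower + upper) / 2
    if (is.null(mean)) mean <- mid
    if (abs(mean - mid) > 1e-9 * max(1, abs(mid)))
      stop("uniform mean must equal the midpoint (lower + upper)/2",
           call. = FALSE)
    sd <- (upper - lower) / sqrt(12)
  }
  if (is.null(mean)) stop("mean is required", call. = FALSE)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("sd must be a single non-negative number", call. = FALSE)
  if (sd == 0 && !kind %in% c("point", "uniform"))
    stop("sd = 0 is permitted only for kind = point", call. = FALSE)
  if (kind == "point") sd <- 0
  if (kind == "truncated_normal") {
    if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
      stop("truncated_normal requires finite lower < upper", call. = FALSE)
    if (sd <= 0) stop("truncated_normal requires sd > 0", call. = FALSE)
  }
  if (lower > mean || mean > upper)
    stop("bounds must satisfy lower <= mean <= upper", call. = FALSE)
  structure(list(kind = kind, mean = mean, sd = sd,
                 lower = lower, upper = upper),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @param value the fixed value of a point parameter.
#' @export
dist_point <- function(value) dist_spec("point", value)

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd) dist_spec("normal", mean, sd)

#' @rdname dist_spec
#' @export
dist_truncnorm <- function(mean, sd, lower, upper)
  dist_spec("truncated_normal", mean, sd, lower, upper)

#' @rdname dist_spec
#' @export
dist_uniform <- function(lower, upper) dist_spec("uniform", lower = lower,
                                                 upper = upper)

#' @export
print.dist_spec <- function(x, ...) {
  b <- if (is.finite(x$lower) || is.finite(x$upper))
    sprintf(" on [%g, %g]", x$lower, x$upper) else ""
  cat(sprintf("<dist_spec> %s(mean = %g, sd = %g)%s\n",
              x$kind, x$mean, x$sd, b))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Standard deviation from a symmetric confidence interval
#'
#' Converts the half-width of a symmetric two-sided normal confidence
#' interval into the standard deviation of the underlying normal:
#' `sd = half_width / z`, where `z` is the two-sided standard-normal
#' quantile at the given confidence level. Used, for example, to turn a
#' stated 95% CI of GBP 10--20/kg about a GBP 15/kg mean protein price into
#' its sampling sd.
#'
#' @param half_width half the CI width, in the units of the parameter (> 0).
#' @param confidence two-sided coverage, in (0, 1). Default 0.95.
#' @return the standard deviation.
#' @examples
#' sd_from_ci(5, 0.95)   # ~2.551
#' @export
sd_from_ci <- function(half_width, confidence = 0.95) {
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(half_width) || half_width < 0)
    stop("half_width must be >= 0", call. = FALSE)
  half_width / stats::qnorm(1 - (1 - confidence) / 2)
}

#' Median of a declared distribution
#'
#' The deterministic central value used whenever the model is evaluated
#' "at medians": point and normal return the mean, uniform the midpoint,
#' and truncated normal the exact median of the truncated law (equal to the
#' mean when the bounds are symmetric about it).
#'
#' @param spec a [dist_spec()].
#' @return a single number.
#' @export
dist_median <- function(spec) {
  stopifnot(is_dist_spec(spec))
  switch(spec$kind,
    point = spec$mean,
    normal = spec$mean,
    uniform = (spec$lower + spec$upper) / 2,
    truncated_normal = {
      pa <- stats::pnorm(spec$lower, spec$mean, spec$sd)
      pb <- stats::pnorm(spec$upper, spec$mean, spec$sd)
      stats::qnorm(pa + 0.5 * (pb - pa), spec$mean, spec$sd)
    })
}

#' Bounds of a declared distribution
#'
#' The low/high values used for one-at-a-time sensitivity ranges: the
#' truncation limits when finite, otherwise the central 95% interval of an
#' untruncated normal, or the point value itself.
#'
#' @param spec a [dist_spec()].
#' @return numeric vector `c(low, high)`.
#' @export
dist_bounds <- function(spec) {
  stopifnot(is_dist_spec(spec))
  if (spec$kind == "point") return(c(spec$mean, spec$mean))
  if (is.finite(spec$lower) && is.finite(spec$upper))
    return(c(spec$lower, spec$upper))
  z <- stats::qnorm(0.975)
  c(spec$mean - z * spec$sd, spec$mean + z * spec$sd)
}

#' Draw samples from a declared distribution
#'
#' Draws from the current RNG stream (callers control reproducibility via
#' `set.seed()` or a [mc_config()] seed). Truncated-normal draws honour the
#' truncation policy: `"resample"` (default) draws from the exact truncated
#' law via the inverse-CDF transform, so every draw lies strictly inside the
#' bounds and no probability mass accumulates at them; `"clip"` draws from
#' the untruncated normal and clamps to the bounds, which does place atoms
#' there and is provided for comparison only.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @param policy `"resample"` or `"clip"` (truncated normal only).
#' @return numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n, policy = c("resample", "clip")) {
  stopifnot(is_dist_spec(spec), n >= 0)
  policy <- match.arg(policy)
  switch(spec$kind,
    point = rep(spec$mean, n),
    normal = stats::rnorm(n, spec$mean, spec$sd),
    uniform = stats::runif(n, spec$lower, spec$upper),
    truncated_normal = {
      if (policy == "clip") {
        pmin(pmax(stats::rnorm(n, spec$mean, spec$sd), spec$lower), spec$upper)
      } else {
        pa <- stats::pnorm(spec$lower, spec$mean, spec$sd)
        pb <- stats::pnorm(spec$upper, spec$mean, spec$sd)
        stats::qnorm(pa + stats::runif(n) * (pb - pa), spec$mean, spec$sd)
      }
    })
}

# dist_spec <-> plain list, for YAML/JSON round-tripping
dist_to_list <- function(spec) {
  out <- list(kind = spec$kind, mean = spec$mean)
  if (spec$kind %in% c("normal", "truncated_normal")) out$sd <- spec$sd
  if (is.finite(spec$lower)) out$lower <- spec$lower
  if (is.finite(spec$upper)) out$upper <- spec$upper
  out
}

dist_from_list <- function(x, path = "<dist>") {
  if (is_dist_spec(x)) return(x)
  if (!is.list(x) || is.null(x$kind))
    stop(sprintf("%s: not a distribution specification (missing 'kind')",
                 path), call. = FALSE)
  tryCatch(
    dist_spec(x$kind,
              mean  = x$mean,
              sd    = if (is.null(x$sd)) 0 else x$sd,
              lower = if (is.null(x$lower)) -Inf else x$lower,
              upper = if (is.null(x$upper)) Inf else x$upper),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
}
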