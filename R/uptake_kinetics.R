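# Empirical glucose-uptake limitation: at high cell density algal cultures
# take up glucose more slowly than growth demand predicts. A polynomial in
# accumulated biomass (or biomass concentration) is fit to observed uptake
# rates and imposed as an upper bound on the glucose uptake flux.

#' Fit a polynomial uptake-capacity curve
#'
#' Ordinary least-squares polynomial of `uptake_rate` (mmol/gDW/h) against a
#' biomass axis — either integrated biomass (gDW/L * h) or biomass
#' concentration (gDW/L). Evaluation of the fitted cap is clipped below at 0,
#' since uptake capacity cannot be negative.
#'
#' @param biomass_axis numeric regressor values.
#' @param uptake_rate numeric uptake fluxes, same length.
#' @param degree polynomial degree (default 2, the lowest degree capturing
#'   saturation followed by decline).
#' @param regressor `"integrated_biomass"` or `"biomass_concentration"`,
#'   recorded on the model.
#' @return an `uptake_cap_model`: list with `coeffs` (ascending powers),
#'   `degree`, `r_squared`, `regressor`.
#' @export
fit_uptake_cap <- function(biomass_axis, uptake_rate, degree = 2,
                           regressor = c("integrated_biomass",
                                         "biomass_concentration")) {
  regressor <- match.arg(regressor)
  if (length(biomass_axis) != length(uptake_rate)) {
    stop("biomass_axis and uptake_rate must have equal length")
  }
  if (degree < 1) stop("degree must be >= 1")
  if (length(biomass_axis) < degree + 1) {
    stop("need at least degree + 1 = ", degree + 1, " points")
  }
  if (diff(range(biomass_axis)) < 1e-12) {
    stop("biomass_axis is (numerically) constant; fit is degenerate")
  }
  fit <- stats::lm(uptake_rate ~ stats::poly(biomass_axis, degree, raw = TRUE))
  coeffs <- unname(stats::coef(fit))
  if (anyNA(coeffs)) stop("underdetermined fit (collinear polynomial basis)")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((uptake_rate - mean(uptake_rate))^2)
  r2 <- if (ss_tot < 1e-300) 1 else 1 - ss_res / ss_tot
  structure(list(coeffs = coeffs, degree = degree, r_squared = r2,
                 regressor = regressor),
            class = "uptake_cap_model")
}

#' Evaluate an uptake-capacity curve
#'
#' @param cap an `uptake_cap_model`.
#' @param x biomass-axis value(s).
#' @return non-negative uptake capacity (mmol/gDW/h), clipped below at 0.
#' @export
eval_uptake_cap <- function(cap, x) {
  stopifnot(inherits(cap, "uptake_cap_model"))
  p <- outer(x, seq_along(cap$coeffs) - 1, `^`)
  pmax(0, as.numeric(p %*% cap$coeffs))
}

#' @export
print.uptake_cap_model <- function(x, ...) {
  cat("<uptake_cap_model> degree ", x$degree, " in ", x$regressor,
      ", R^2 = ", format(x$r_squared, digits = 4), "\n", sep = "")
  cat("  coeffs (ascending): ",
      paste(format(x$coeffs, digits = 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Impose an uptake cap on a model variant's glucose uptake
#'
#' Sets the glucose uptake upper bound to `max(0, cap(x))` evaluated at the
#' current biomass-axis value. Other bounds are untouched; a modified copy is
#' returned.
#'
#' @param variant a [model_variant()] with a mapped `glucose` uptake.
#' @param cap an `uptake_cap_model`.
#' @param biomass_axis_value current value of the cap's regressor.
#' @return the modified [model_variant()].
#' @export
apply_uptake_cap <- function(variant, cap, biomass_axis_value) {
  stopifnot(inherits(variant, "model_variant"))
  net <- variant$network
  if (!"glucose" %in% names(net$uptake_rxns)) {
    stop("variant has no mapped glucose uptake reaction")
  }
  rxn <- net$uptake_rxns[["glucose"]]
  val <- eval_uptake_cap(cap, biomass_axis_value)
  net <- set_bounds(net, rxn, lb = min(net$lb[[rxn]], val), ub = val)
  variant$network <- net
  variant
}

#' Serialize / deserialize an uptake-cap model to JSON
#'
#' @param cap an `uptake_cap_model`.
#' @param path output file; `NULL` returns the JSON string.
#' @return `path` invisibly, or the JSON string.
#' @export
cap_to_json <- function(cap, path = NULL) {
  stopifnot(inherits(cap, "uptake_cap_model"))
  txt <- jsonlite::toJSON(unclass(cap), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname cap_to_json
#' @export
cap_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(coeffs = as.numeric(obj$coeffs),
                 degree = as.integer(obj$degree),
                 r_squared = as.numeric(obj$r_squared),
                 regressor = obj$regressor),
            class = "uptake_cap_model")
}

#' Derive uptake-rate observations from a culture time series
#'
#' Converts medium glucose measurements into per-interval volumetric
#' consumption rates, then into specific uptake fluxes using the mean biomass
#' over each interval, and accumulates the integrated-biomass axis by
#' trapezoidal quadrature. Intervals in which glucose increased (a feed
#' event) are dropped.
#'
#' @param time_h sampling times (h), strictly increasing.
#' @param biomass_gdw_l biomass concentrations (gDW/L).
#' @param glucose_mg_l medium glucose concentrations (mg/L).
#' @param mw glucose molecular weight (mg/mmol), default 180.16.
#' @return data.frame with `integrated_biomass`, `biomass_concentration`,
#'   `uptake_flux` (mmol/gDW/h), one row per usable interval.
#' @export
uptake_series <- function(time_h, biomass_gdw_l, glucose_mg_l, mw = 180.16) {
  stopifnot(length(time_h) == length(biomass_gdw_l),
            length(time_h) == length(glucose_mg_l),
            all(diff(time_h) > 0))
  dt <- diff(time_h)
  xbar <- (utils::head(biomass_gdw_l, -1) + utils::tail(biomass_gdw_l, -1)) / 2
  dglc <- diff(glucose_mg_l)
  ib <- cumsum(c(0, xbar * dt))  # gDW/L * h, trapezoid
  flux <- (-dglc / dt) / (mw * xbar)
  keep <- dglc <= 0
  data.frame(integrated_biomass = utils::tail(ib, -1)[keep],
             biomass_concentration = utils::tail(biomass_gdw_l, -1)[keep],
             uptake_flux = flux[keep])
}
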