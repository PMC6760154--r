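# The metabolic model control loop: optical density -> growth rate ->
# growth-constrained uptake minimization -> feed mass for the next interval.

#' Optical density time series
#'
#' @param times sampling times (h), strictly increasing.
#' @param od750 optical density at 750 nm, all positive.
#' @param od_to_gdw conversion factor, gDW/L per OD750 unit. The default 0.4
#'   is an approximate pairing of OD750 ~ 1.3 with ~520 mg/L dry biomass in
#'   late-stage nitrogen-limited cultures; override for a calibrated
#'   instrument.
#' @return an `od_series`.
#' @export
od_series <- function(times, od750, od_to_gdw = 0.4) {
  stopifnot(length(times) == length(od750))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od750 <= 0)) stop("od750 values must be positive")
  if (od_to_gdw <= 0) stop("od_to_gdw must be positive")
  structure(list(times = as.numeric(times), od750 = as.numeric(od750),
                 od_to_gdw = od_to_gdw),
            class = "od_series")
}

#' Read an OD/nutrient observation CSV
#'
#' Expected columns: `time_h`, `od750`, optionally `nitrate_mg_L`,
#' `glucose_mg_L`.
#'
#' @param path CSV file.
#' @param od_to_gdw passed to [od_series()].
#' @return list with `series` (an `od_series`) and `data` (the data.frame).
#' @export
read_od_csv <- function(path, od_to_gdw = 0.4) {
  df <- utils::read.csv(path)
  need <- c("time_h", "od750")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("CSV lacks column(s): ", paste(miss, collapse = ", "))
  list(series = od_series(df$time_h, df$od750, od_to_gdw), data = df)
}

series_od_at <- function(series, t, tol = 1e-8) {
  i <- which(abs(series$times - t) <= tol)
  if (!length(i)) stop("no observation at t = ", t, " h")
  series$od750[[i[1]]]
}

#' Estimate the specific growth rate from two OD observations
#'
#' `mu = ln(OD_t / OD_t-1) / (t_now - t_prev)`, the exponential-phase
#' estimator used between consecutive feeding time points.
#'
#' @param series an [od_series()].
#' @param t_prev,t_now observation times (h), both present in the series,
#'   `t_now > t_prev`.
#' @return a `growth_estimate`: list with `mu` (1/h), `window`,
#'   `negative` flag.
#' @export
estimate_growth_rate <- function(series, t_prev, t_now) {
  stopifnot(inherits(series, "od_series"))
  if (t_now <= t_prev) stop("t_now must exceed t_prev")
  od0 <- series_od_at(series, t_prev)
  od1 <- series_od_at(series, t_now)
  mu <- log(od1 / od0) / (t_now - t_prev)
  structure(list(mu = mu, window = c(t_prev, t_now), negative = mu < 0),
            class = "growth_estimate")
}

#' Nutrient specification for flux-to-mass conversion
#'
#' @param name nutrient name as used in the network's uptake map.
#' @param molecular_weight mg/mmol. Defaults: nitrate (NO3-) 62.00, glucose
#'   180.16.
#' @param uptake_rxn optional reaction id override (otherwise resolved
#'   through the network's uptake map by `name`).
#' @return a `nutrient_spec`.
#' @export
nutrient_spec <- function(name,
                          molecular_weight = c(nitrate = 62.00,
                                               glucose = 180.16)[[name]],
                          uptake_rxn = NULL) {
  if (is.null(molecular_weight) || is.na(molecular_weight) ||
      molecular_weight <= 0) {
    stop("molecular_weight must be positive for nutrient '", name, "'")
  }
  structure(list(name = name, molecular_weight = molecular_weight,
                 uptake_rxn = uptake_rxn),
            class = "nutrient_spec")
}

#' Convert an uptake flux into a feed mass for the next interval
#'
#' Integrates `flux * MW * X(t)` over the interval assuming biomass grows
#' exponentially at `mu` from `X0`:
#' `mass = flux * MW * X0 * (exp(mu dt) - 1) / mu` (mg/L), with the limit
#' `flux * MW * X0 * dt` used when `|mu| < 1e-9`. A constant-biomass variant
#' is available via `method = "constant"`.
#'
#' @param flux uptake flux, mmol/gDW/h (non-negative).
#' @param nutrient a [nutrient_spec()].
#' @param X0 biomass concentration at interval start, gDW/L.
#' @param mu growth rate over the interval, 1/h (negative allowed: shrinking
#'   biomass integrates the same closed form).
#' @param dt interval length, h.
#' @param method `"exponential"` (default) or `"constant"`.
#' @return feed mass concentration to add, mg/L.
#' @export
flux_to_feed_mass <- function(flux, nutrient, X0, mu, dt,
                              method = c("exponential", "constant")) {
  method <- match.arg(method)
  stopifnot(inherits(nutrient, "nutrient_spec"))
  if (flux < 0 || X0 < 0 || dt < 0) stop("flux, X0 and dt must be >= 0")
  mw <- nutrient$molecular_weight
  if (method == "constant" || abs(mu) < 1e-9) {
    return(flux * mw * X0 * dt)
  }
  flux * mw * X0 * (exp(mu * dt) - 1) / mu
}

new_feed_prediction <- function(nutrient, interval, uptake_flux,
                                feed_mass_conc, scale_factor, mu, flags) {
  structure(list(nutrient = nutrient, interval = interval,
                 uptake_flux = uptake_flux, feed_mass_conc = feed_mass_conc,
                 scale_factor = scale_factor, mu = mu, flags = flags),
            class = "feed_prediction")
}

#' @export
print.feed_prediction <- function(x, ...) {
  cat(sprintf("<feed_prediction> %s [%g, %g] h: %.4g mg/L (flux %.4g, mu %.4g%s)\n",
              x$nutrient, x$interval[1], x$interval[2], x$feed_mass_conc,
              x$uptake_flux, x$mu,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Largest growth rate the model currently supports
#'
#' Returns `min(mu_target, max achievable growth)` under the variant's
#' current bounds; used whenever fixing the biomass flux to the OD-estimated
#' growth rate would be infeasible (e.g. under a binding glucose-uptake cap).
#'
#' @param variant a [model_variant()].
#' @param mu_target requested growth rate (1/h).
#' @return a feasible growth rate (1/h).
#' @export
feasible_growth <- function(variant, mu_target) {
  sol <- maximize_growth(variant)
  if (sol$status != "optimal") return(0)
  min(mu_target, sol$objective_value)
}

#' Predict the single-nutrient feed for the next interval (autotrophic MMC)
#'
#' Chains [estimate_growth_rate()] over `(t_prev, t_now)`,
#' [minimize_uptake_at_growth()] at the estimated rate, and
#' [flux_to_feed_mass()] over `(t_now, t_now + dt_next)` with
#' `X0 = od750(t_now) * od_to_gdw`, finally multiplying the mass by `scale`
#' (feeding e.g. 80/100/120% of the predicted optimum).
#'
#' @param variant a [model_variant()].
#' @param series an [od_series()].
#' @param t_prev,t_now growth-estimation window (h).
#' @param dt_next length of the upcoming feed interval (h).
#' @param nutrient a [nutrient_spec()] (default nitrate).
#' @param scale feed scaling factor, > 0 (default 1).
#' @param mu_floor below this growth rate the feed is 0 and the prediction is
#'   flagged (`"mu_floor"`); default 0: never feed a shrinking culture.
#' @return a `feed_prediction`.
#' @export
predict_feed_autotrophic <- function(variant, series, t_prev, t_now, dt_next,
                                     nutrient = nutrient_spec("nitrate"),
                                     scale = 1, mu_floor = 0) {
  if (scale <= 0) stop("scale must be positive")
  est <- estimate_growth_rate(series, t_prev, t_now)
  X0 <- series_od_at(series, t_now) * series$od_to_gdw
  flags <- character()
  mu <- est$mu
  if (mu <= mu_floor) {
    return(new_feed_prediction(nutrient$name, c(t_now, t_now + dt_next),
                               0, 0, scale, mu, "mu_floor"))
  }
  mu_ok <- feasible_growth(variant, mu)
  if (mu_ok < mu - 1e-12) flags <- c(flags, "growth_capped")
  sol <- minimize_uptake_at_growth(variant, nutrient$name, mu_ok)
  if (sol$status != "optimal") {
    return(new_feed_prediction(nutrient$name, c(t_now, t_now + dt_next),
                               NA_real_, NA_real_, scale, mu,
                               c(flags, "infeasible")))
  }
  mass <- flux_to_feed_mass(max(0, sol$objective_value), nutrient, X0,
                            mu_ok, dt_next) * scale
  new_feed_prediction(nutrient$name, c(t_now, t_now + dt_next),
                      sol$objective_value, mass, scale, mu_ok, flags)
}

#' Predict glucose and nitrate feeds (heterotrophic MMC)
#'
#' Applies the empirical glucose-uptake cap (when given) at the current
#' biomass-axis value, reduces the OD-estimated growth rate to what the
#' capped model supports ([feasible_growth()]), runs
#' [lexicographic_minimize()] in the order glucose-then-nitrate, and converts
#' each minimized flux to a feed mass.
#'
#' @param variant a heterotrophic [model_variant()].
#' @param series an [od_series()].
#' @param t_prev,t_now growth-estimation window (h).
#' @param dt_next upcoming feed interval (h).
#' @param nutrients list of two [nutrient_spec()]s, glucose then nitrate.
#' @param cap optional `uptake_cap_model`.
#' @param biomass_axis_value value of the cap's regressor at `t_now`
#'   (defaults to current biomass concentration).
#' @param scale feed scaling factor (applied to both nutrients).
#' @param mu_floor as in [predict_feed_autotrophic()].
#' @return list of two `feed_prediction`s (glucose, nitrate).
#' @export
predict_feeds_heterotrophic <- function(variant, series, t_prev, t_now,
                                        dt_next,
                                        nutrients = list(
                                          nutrient_spec("glucose"),
                                          nutrient_spec("nitrate")),
                                        cap = NULL,
                                        biomass_axis_value = NULL,
                                        scale = 1, mu_floor = 0) {
  if (variant$trophic_mode != "heterotrophic") {
    stop("heterotrophic prediction requires a heterotrophic variant")
  }
  est <- estimate_growth_rate(series, t_prev, t_now)
  X0 <- series_od_at(series, t_now) * series$od_to_gdw
  order <- vapply(nutrients, `[[`, "", "name")
  interval <- c(t_now, t_now + dt_next)
  if (est$mu <= mu_floor) {
    return(lapply(order, function(nm)
      new_feed_prediction(nm, interval, 0, 0, scale, est$mu, "mu_floor")))
  }
  flags <- character()
  if (!is.null(cap)) {
    variant <- apply_uptake_cap(variant, cap,
                                biomass_axis_value %||% X0)
  }
  mu_ok <- feasible_growth(variant, est$mu)
  if (mu_ok < est$mu - 1e-12) flags <- c(flags, "growth_capped")
  fluxes <- lexicographic_minimize(variant, mu_ok, order = order)
  lapply(seq_along(nutrients), function(i) {
    nsp <- nutrients[[i]]
    mass <- flux_to_feed_mass(max(0, fluxes[[i]]), nsp, X0, mu_ok,
                              dt_next) * scale
    new_feed_prediction(nsp$name, interval, fluxes[[i]], mass, scale,
                        mu_ok, flags)
  })
}

#' Run the controller over a schedule of feed times
#'
#' At each feed time the latest two observations at or before that time give
#' the growth estimate, and the interval to the next feed time (or `horizon`)
#' gives the feed window. Failures at individual time points are flagged and
#' recorded, not fatal.
#'
#' @param variant a [model_variant()].
#' @param series an [od_series()] covering the feed times.
#' @param feed_times feeding time points (h).
#' @param config list: `scale`, `mu_floor`, `nutrients` (list of
#'   [nutrient_spec()]; length 1 for single-nutrient control, 2 for
#'   glucose+nitrate), `cap` (optional `uptake_cap_model`), `horizon`
#'   (end of last interval; default last feed time + median spacing).
#' @return a `feed_schedule`: list with `predictions`, `table` (data.frame
#'   time_h/nutrient/feed_mg_L/uptake_flux/mu/flags), and `ledger`
#'   (a [feed_ledger()]).
#' @export
run_schedule <- function(variant, series, feed_times, config = list()) {
  stopifnot(inherits(series, "od_series"))
  feed_times <- sort(feed_times)
  scale <- config$scale %||% 1
  mu_floor <- config$mu_floor %||% 0
  nutrients <- config$nutrients %||% list(nutrient_spec("nitrate"))
  hetero <- length(nutrients) > 1
  spacing <- if (length(feed_times) > 1) stats::median(diff(feed_times)) else
    config$dt %||% 24
  horizon <- config$horizon %||% (max(feed_times) + spacing)
  ledger <- feed_ledger(initial = config$initial %||% numeric())

  preds <- list()
  rows <- list()
  for (k in seq_along(feed_times)) {
    tk <- feed_times[[k]]
    dt_next <- (if (k < length(feed_times)) feed_times[[k + 1]] else horizon) - tk
    obs <- series$times[series$times <= tk + 1e-8]
    if (length(obs) < 2) {
      rows[[length(rows) + 1]] <- data.frame(
        time_h = tk, nutrient = nutrients[[1]]$name, feed_mg_L = NA_real_,
        uptake_flux = NA_real_, mu = NA_real_, flags = "no_observations")
      next
    }
    t_now <- obs[length(obs)]
    t_prev <- obs[length(obs) - 1]
    pk <- tryCatch({
      if (hetero) {
        predict_feeds_heterotrophic(variant, series, t_prev, t_now, dt_next,
                                    nutrients = nutrients, cap = config$cap,
                                    scale = scale, mu_floor = mu_floor)
      } else {
        list(predict_feed_autotrophic(variant, series, t_prev, t_now, dt_next,
                                      nutrient = nutrients[[1]],
                                      scale = scale, mu_floor = mu_floor))
      }
    }, error = function(e) e)
    if (inherits(pk, "error")) {
      rows[[length(rows) + 1]] <- data.frame(
        time_h = tk, nutrient = nutrients[[1]]$name, feed_mg_L = NA_real_,
        uptake_flux = NA_real_, mu = NA_real_,
        flags = paste0("error:", conditionMessage(pk)))
      next
    }
    for (p in pk) {
      preds[[length(preds) + 1]] <- p
      if (is.finite(p$feed_mass_conc) && p$feed_mass_conc > 0) {
        ledger <- add_feed(ledger, p$nutrient, tk, p$feed_mass_conc)
      }
      rows[[length(rows) + 1]] <- data.frame(
        time_h = tk, nutrient = p$nutrient, feed_mg_L = p$feed_mass_conc,
        uptake_flux = p$uptake_flux, mu = p$mu,
        flags = paste(p$flags, collapse = ";"))
    }
  }
  structure(list(predictions = preds,
                 table = do.call(rbind, rows) %||%
                   data.frame(time_h = numeric(), nutrient = character(),
                              feed_mg_L = numeric(), uptake_flux = numeric(),
                              mu = numeric(), flags = character()),
                 ledger = ledger),
            class = "feed_schedule")
}

#' @export
print.feed_schedule <- function(x, ...) {
  cat("<feed_schedule> ", length(x$predictions), " predictions\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Read a controller run configuration (JSON or YAML)
#'
#' Recognized fields: `scale`, `dt`, `od_to_gdw`, `mu_floor`, `initial`,
#' `nutrients` (map name -> {mw, rxn}), `cap` ({degree, coeffs} or
#' {fit_from: csv}).
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return a config list with `nutrients` as [nutrient_spec()]s and `cap` as
#'   an `uptake_cap_model` when given.
#' @export
read_mmc_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- raw
  if (!is.null(raw$nutrients)) {
    cfg$nutrients <- lapply(names(raw$nutrients), function(nm) {
      spec <- raw$nutrients[[nm]]
      nutrient_spec(nm,
                    molecular_weight = spec$mw %||%
                      c(nitrate = 62.00, glucose = 180.16)[[nm]],
                    uptake_rxn = spec$rxn)
    })
  }
  if (!is.null(raw$cap) && !is.null(raw$cap$coeffs)) {
    cfg$cap <- structure(list(coeffs = as.numeric(raw$cap$coeffs),
                              degree = length(raw$cap$coeffs) - 1L,
                              r_squared = NA_real_,
                              regressor = raw$cap$regressor %||%
                                "integrated_biomass"),
                         class = "uptake_cap_model")
  }
  cfg
}
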