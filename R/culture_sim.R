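# Virtual algal culture: a discrete-time quota (Droop-flavored) model
# reproducing the phenomenology the feed controller relies on — exponential
# growth, nutrient exhaustion, glucose-uptake saturation at high density,
# and growth cessation once protein content falls to ~10% of dry weight.

MW_NITRATE <- 62.00
MW_GLUCOSE <- 180.16

#' Virtual-cell parameters
#'
#' The cell grows at `mu_max` scaled by a linear protein-quota factor
#' `(p - p_min) / (p_target - p_min)` (clipped to `[0, 1]`) and gated off
#' entirely below `p_min`. Nitrogen uptake replenishes the protein pool
#' toward `p_target`; when the medium is empty, protein degrades at `k_deg`
#' (recycling into storage products), which is what eventually drives the
#' quota below the growth threshold under starvation.
#'
#' @param mu_max maximal specific growth rate (1/h).
#' @param composition a [biomass_composition()]; sets the nitrogen demand
#'   per gDW (`sum(fractions * n_content)`), the glucose demand per gDW
#'   (carbon plus respiration), and `p_target = fractions["amino_acid"]`.
#' @param p_min protein mass fraction below which growth stops (default
#'   0.10).
#' @param p0 initial protein fraction (default `p_target`).
#' @param v_n_max maximal nitrate uptake flux (mmol/gDW/h).
#' @param v_g_cap maximal glucose uptake flux: a constant, or an
#'   `uptake_cap_model` evaluated on its recorded regressor.
#' @param k_deg protein degradation rate under nitrogen exhaustion (1/h).
#' @param syn_atp ATP cost per gram macromolecule (matches the toy model's
#'   respiration bookkeeping; default 0.5).
#' @param noise_sd multiplicative lognormal OD noise sigma (0 = noiseless).
#' @param od_to_gdw OD750 to gDW/L conversion (default 0.4).
#' @return a `cell_params`.
#' @export
cell_params <- function(mu_max = 0.02,
                        composition = default_composition("PAT1"),
                        p_min = 0.10, p0 = NULL,
                        v_n_max = 1, v_g_cap = Inf,
                        k_deg = 0.005, syn_atp = 0.5,
                        noise_sd = 0, od_to_gdw = 0.4) {
  stopifnot(mu_max > 0, p_min > 0, v_n_max > 0, k_deg >= 0, od_to_gdw > 0)
  dem <- biomass_demand(composition)
  p_target <- composition$fractions[["amino_acid"]]
  if (p_min >= p_target && is.null(p0)) {
    stop("p_min must be below the composition's amino-acid fraction (p_target)")
  }
  n_aa <- composition$n_content[["amino_acid"]]
  if (n_aa <= 0) stop("composition must place nitrogen in amino acids")
  demand_g <- dem[["C"]] / 6 + syn_atp / 30  # mmol glucose per gDW
  structure(list(mu_max = mu_max, composition = composition,
                 p_min = p_min, p_target = p_target,
                 p0 = p0 %||% p_target,
                 demand_n = dem[["N"]], demand_g = demand_g, n_aa = n_aa,
                 v_n_max = v_n_max, v_g_cap = v_g_cap, k_deg = k_deg,
                 noise_sd = noise_sd, od_to_gdw = od_to_gdw),
            class = "cell_params")
}

#' Culture state
#'
#' @param t time (h).
#' @param X biomass (gDW/L), positive.
#' @param S_N medium nitrate (mg/L).
#' @param S_G medium glucose (mg/L).
#' @param p protein mass fraction in `[0, 1]`.
#' @param ib integrated biomass so far (gDW/L * h), the glucose-cap
#'   regressor.
#' @return a `culture_state`.
#' @export
culture_state <- function(t = 0, X, S_N = 0, S_G = 0, p, ib = 0) {
  stopifnot(X > 0, S_N >= 0, S_G >= 0, p >= 0, p <= 1)
  structure(list(t = t, X = X, S_N = S_N, S_G = S_G, p = p, ib = ib),
            class = "culture_state")
}

glucose_cap_flux <- function(params, state) {
  cap <- params$v_g_cap
  if (inherits(cap, "uptake_cap_model")) {
    x <- if (cap$regressor == "integrated_biomass") state$ib else state$X
    eval_uptake_cap(cap, x)
  } else {
    cap
  }
}

#' Advance the virtual culture by one time step
#'
#' Feeds are added to the medium pools first. Realized growth is
#' `mu_max * quota_factor`, further limited (heterotrophy) by the glucose
#' pool and the uptake cap; biomass is updated exponentially within the
#' step. Nitrogen uptake then replenishes the protein pool toward
#' `p_target`, bounded by the uptake capacity and the medium pool; with an
#' empty pool the protein fraction is diluted by growth and degraded at
#' `k_deg`. Pool bookkeeping is exact: `pool_out = pool_in + feed - uptake`.
#'
#' @param state a [culture_state()].
#' @param params a [cell_params()].
#' @param dt step length (h), > 0.
#' @param feeds named numeric, mg/L added at step start (names `nitrate`,
#'   `glucose`).
#' @param heterotrophic if `TRUE`, growth requires medium glucose.
#' @return the next `culture_state`, with attribute `uptake` (named mg/L).
#' @export
sim_step <- function(state, params, dt, feeds = numeric(),
                     heterotrophic = FALSE) {
  stopifnot(dt > 0)
  S_N <- state$S_N + (if ("nitrate" %in% names(feeds)) feeds[["nitrate"]] else 0)
  S_G <- state$S_G + (if ("glucose" %in% names(feeds)) feeds[["glucose"]] else 0)
  X <- state$X
  p <- state$p
  P <- p * X

  quota <- if (p >= params$p_min) {
    min(1, (p - params$p_min) / (params$p_target - params$p_min))
  } else 0
  mu <- params$mu_max * quota

  if (heterotrophic && mu > 0) {
    v_cap <- glucose_cap_flux(params, state)
    mu_cap <- v_cap / params$demand_g
    avail_g <- S_G / MW_GLUCOSE                       # mmol/L
    mu_pool <- log1p(avail_g / (params$demand_g * X)) / dt
    mu <- max(0, min(mu, mu_cap, mu_pool))
  }

  X_new <- X * exp(mu * dt)
  dX <- X_new - X
  int_x <- if (mu > 1e-12) dX / mu else X * dt        # integral of X over step

  U_G <- if (heterotrophic) min(params$demand_g * dX, S_G / MW_GLUCOSE) else 0

  desired_n <- max(0, (params$p_target * X_new - P) * params$n_aa)
  U_N <- min(desired_n, params$v_n_max * int_x, S_N / MW_NITRATE)

  P_new <- P + U_N / params$n_aa
  pool_n_left <- S_N - U_N * MW_NITRATE
  if (U_N * MW_NITRATE < 1e-9 && pool_n_left < 1e-9) {
    P_new <- max(0, P_new - params$k_deg * P * dt)    # starvation recycling
  }

  out <- culture_state(t = state$t + dt, X = X_new,
                       S_N = S_N - U_N * MW_NITRATE,
                       S_G = S_G - U_G * MW_GLUCOSE,
                       p = min(1, P_new / X_new),
                       ib = state$ib + int_x)
  attr(out, "uptake") <- c(nitrate = U_N * MW_NITRATE,
                           glucose = U_G * MW_GLUCOSE)
  attr(out, "mu") <- mu
  out
}

#' Run a feeding strategy against the virtual culture
#'
#' Alternates simulator steps with controller predictions at the configured
#' feed times. Observations (OD, optionally noisy) are taken at time 0 and
#' at every feed time; the controller sees only those.
#'
#' Strategies: `"mmc"` — growth estimated from the last two observations,
#' feed from growth-constrained uptake minimization; `"biorule"` — feed
#' computed from a fixed growth-rate guess (`mu_bio`) instead of
#' measurements; `"bulk"` — no feeding beyond the initial charge.
#'
#' @param params a [cell_params()].
#' @param variant the controller's [model_variant()] (its composition may
#'   deliberately mismatch `params` for robustness experiments).
#' @param config list: `strategy` (mmc/bulk/biorule), `feed_times` (h),
#'   `scale`, `initial` named charges mg/L, `X0` gDW/L, `dt_sim` (default
#'   0.5 h), `horizon` h, `nutrients` (list of [nutrient_spec()]),
#'   `cap` (`uptake_cap_model`), `mu_bio` (default 0.0137), `mu_floor`,
#'   `seed` for observation noise.
#' @param horizon simulation end (h); overrides `config$horizon`.
#' @return list with `trajectory` (data.frame time_h, od750, X_gDW_L,
#'   nitrate_mg_L, glucose_mg_L, protein_frac), `ledger`, `feeds`
#'   (data.frame), `final_state`, `observations`.
#' @export
run_closed_loop <- function(params, variant = NULL, config = list(),
                            horizon = NULL) {
  stopifnot(inherits(params, "cell_params"))
  strategy <- config$strategy %||% "mmc"
  horizon <- horizon %||% config$horizon %||% 168
  dt_sim <- config$dt_sim %||% 0.5
  feed_times <- config$feed_times %||% seq(24, horizon - 1e-9, by = 24)
  if (strategy == "bulk") feed_times <- numeric()
  scale <- config$scale %||% 1
  mu_floor <- config$mu_floor %||% 0
  initial <- config$initial %||% c(nitrate = 0)
  hetero <- !is.null(variant) && variant$trophic_mode == "heterotrophic"
  nutrients <- config$nutrients %||% (
    if (hetero) list(nutrient_spec("glucose"), nutrient_spec("nitrate"))
    else list(nutrient_spec("nitrate")))
  if (!is.null(config$seed)) set.seed(config$seed)

  state <- culture_state(
    t = 0, X = config$X0 %||% 0.032,
    S_N = if ("nitrate" %in% names(initial)) initial[["nitrate"]] else 0,
    S_G = if ("glucose" %in% names(initial)) initial[["glucose"]] else 0,
    p = params$p0)
  ledger <- feed_ledger(initial = initial)

  observe <- function(state) {
    od <- state$X / params$od_to_gdw
    if (params$noise_sd > 0) od <- od * exp(stats::rnorm(1, 0, params$noise_sd))
    od
  }
  obs_t <- 0
  obs_od <- observe(state)

  n_steps <- ceiling(horizon / dt_sim)
  traj <- vector("list", n_steps + 1)
  feeds_log <- list()
  snapshot <- function(state) data.frame(
    time_h = state$t, od750 = state$X / params$od_to_gdw,
    X_gDW_L = state$X, nitrate_mg_L = state$S_N, glucose_mg_L = state$S_G,
    protein_frac = state$p)
  traj[[1]] <- snapshot(state)

  remaining_feeds <- sort(feed_times)
  for (k in seq_len(n_steps)) {
    t_now <- state$t
    feeds <- numeric()
    if (length(remaining_feeds) && t_now >= remaining_feeds[1] - 1e-9) {
      tf <- remaining_feeds[1]
      remaining_feeds <- remaining_feeds[-1]
      nxt <- if (length(remaining_feeds)) remaining_feeds[1] else horizon
      dt_next <- max(nxt - tf, 0)

      obs_t <- c(obs_t, tf)
      obs_od <- c(obs_od, observe(state))
      series <- od_series(obs_t, obs_od, od_to_gdw = params$od_to_gdw)
      np <- length(obs_t)

      preds <- tryCatch({
        if (strategy == "biorule") {
          mu_bio <- config$mu_bio %||% 0.0137
          lapply(nutrients, function(nsp) {
            sol <- minimize_uptake_at_growth(variant, nsp$name, mu_bio)
            X0 <- obs_od[np] * params$od_to_gdw
            mass <- flux_to_feed_mass(max(0, sol$objective_value), nsp, X0,
                                      mu_bio, dt_next) * scale
            new_feed_prediction(nsp$name, c(tf, tf + dt_next),
                                sol$objective_value, mass, scale, mu_bio,
                                character())
          })
        } else if (hetero) {
          predict_feeds_heterotrophic(variant, series, obs_t[np - 1],
                                      obs_t[np], dt_next,
                                      nutrients = nutrients,
                                      cap = config$cap,
                                      biomass_axis_value =
                                        if (!is.null(config$cap) &&
                                            config$cap$regressor ==
                                              "integrated_biomass")
                                          state$ib else NULL,
                                      scale = scale, mu_floor = mu_floor)
        } else {
          list(predict_feed_autotrophic(variant, series, obs_t[np - 1],
                                        obs_t[np], dt_next,
                                        nutrient = nutrients[[1]],
                                        scale = scale, mu_floor = mu_floor))
        }
      }, error = function(e) e)

      if (!inherits(preds, "error")) {
        for (pr in preds) {
          if (is.finite(pr$feed_mass_conc) && pr$feed_mass_conc > 0) {
            feeds[pr$nutrient] <- (if (pr$nutrient %in% names(feeds))
              feeds[[pr$nutrient]] else 0) + pr$feed_mass_conc
            ledger <- add_feed(ledger, pr$nutrient, tf, pr$feed_mass_conc)
            feeds_log[[length(feeds_log) + 1]] <- data.frame(
              time_h = tf, nutrient = pr$nutrient,
              feed_mg_L = pr$feed_mass_conc, mu = pr$mu,
              flags = paste(pr$flags, collapse = ";"))
          }
        }
      } else {
        feeds_log[[length(feeds_log) + 1]] <- data.frame(
          time_h = tf, nutrient = NA_character_, feed_mg_L = NA_real_,
          mu = NA_real_, flags = paste0("error:", conditionMessage(preds)))
      }
    }
    dt_k <- min(dt_sim, horizon - t_now)
    if (dt_k <= 0) break
    state <- sim_step(state, params, dt_k, feeds = feeds,
                      heterotrophic = hetero)
    traj[[k + 1]] <- snapshot(state)
  }

  list(trajectory = do.call(rbind, traj[!vapply(traj, is.null, TRUE)]),
       ledger = ledger,
       feeds = if (length(feeds_log)) do.call(rbind, feeds_log) else
         data.frame(time_h = numeric(), nutrient = character(),
                    feed_mg_L = numeric(), mu = numeric(),
                    flags = character()),
       final_state = state,
       observations = data.frame(time_h = obs_t, od750 = obs_od))
}

#' Add measurement noise to a simulated trajectory
#'
#' OD gets multiplicative lognormal noise; nutrient concentrations get
#' truncated-at-zero Gaussian noise with standard deviation
#' `sigma * value`. Reproducible via `seed`.
#'
#' @param trajectory a trajectory data.frame from [run_closed_loop()].
#' @param sigma relative noise level (0 = exact round-trip).
#' @param seed RNG seed.
#' @param od_to_gdw conversion factor for the returned [od_series()].
#' @return list with `series` (an `od_series`) and `data` (noisy
#'   data.frame).
#' @export
generate_observations <- function(trajectory, sigma = 0, seed = 1,
                                  od_to_gdw = 0.4) {
  set.seed(seed)
  df <- trajectory
  n <- nrow(df)
  if (sigma > 0) {
    df$od750 <- df$od750 * exp(stats::rnorm(n, 0, sigma))
    df$nitrate_mg_L <- pmax(0, stats::rnorm(n, df$nitrate_mg_L,
                                            sigma * pmax(df$nitrate_mg_L, 0)))
    if ("glucose_mg_L" %in% names(df)) {
      df$glucose_mg_L <- pmax(0, stats::rnorm(n, df$glucose_mg_L,
                                              sigma * pmax(df$glucose_mg_L, 0)))
    }
  }
  list(series = od_series(df$time_h, df$od750, od_to_gdw), data = df)
}

#' Write a trajectory CSV
#'
#' @param trajectory trajectory data.frame.
#' @param path output CSV.
#' @return `path` invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
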