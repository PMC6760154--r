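test_that("growth-rate estimation reproduces the exponential-phase formula", {
  ser <- od_series(c(0, 24, 48), c(1, 2, 2))
  expect_equal(estimate_growth_rate(ser, 0, 24)$mu, log(2) / 24,
               tolerance = 1e-12)
  expect_equal(estimate_growth_rate(ser, 24, 48)$mu, 0)
  # OD 1.0 -> 1.3893 over 24 h: the 0.0137 1/h reference rate
  ser2 <- od_series(c(0, 24), c(1.0, 1.3893))
  expect_equal(estimate_growth_rate(ser2, 0, 24)$mu, 0.0137,
               tolerance = 1e-4)
  shrink <- od_series(c(0, 24), c(2, 1))
  est <- estimate_growth_rate(shrink, 0, 24)
  expect_true(est$negative)
  expect_error(estimate_growth_rate(ser, 24, 24), "exceed")
  expect_error(estimate_growth_rate(ser, 0, 36), "no observation")
  expect_error(od_series(c(0, 24), c(1, 0)), "positive")
})

test_that("flux-to-mass conversion matches numerical integration", {
  no3 <- nutrient_spec("nitrate")
  # reference case: ~88.1 mg/L
  m <- flux_to_feed_mass(0.5, no3, X0 = 0.1, mu = 0.0137, dt = 24)
  expect_equal(m, feed_mass_oracle(0.5, 62, 0.1, 0.0137, 24),
               tolerance = 1e-9)
  expect_equal(m, 88.1, tolerance = 0.01)
  # zero-growth limit: plain product
  expect_equal(flux_to_feed_mass(1, no3, 0.1, 0, 24), 148.8,
               tolerance = 1e-9)
  expect_equal(flux_to_feed_mass(0, no3, 0.1, 0.05, 24), 0)
  # grid across mu (including near-zero and negative), dt, X0
  for (mu in c(-0.02, -1e-10, 0, 1e-10, 0.005, 0.05)) {
    for (dt in c(6, 24)) {
      for (X0 in c(0.05, 0.5)) {
        expect_equal(flux_to_feed_mass(0.3, no3, X0, mu, dt),
                     feed_mass_oracle(0.3, 62, X0, mu, dt),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("autotrophic feed prediction composes its pieces", {
  v <- build_toy_model(pat5(), "autotrophic")  # N demand 1.776
  ser <- od_series(c(0, 24), c(1.0, 1.3893), od_to_gdw = 0.4)
  pred <- predict_feed_autotrophic(v, ser, 0, 24, dt_next = 24)
  mu <- log(1.3893) / 24
  expect_equal(pred$mu, mu, tolerance = 1e-12)
  expect_equal(pred$uptake_flux, 1.776 * mu, tolerance = 1e-8)
  X0 <- 1.3893 * 0.4
  expect_equal(pred$feed_mass_conc,
               feed_mass_oracle(1.776 * mu, 62, X0, mu, 24),
               tolerance = 1e-6)
  # linear in the feed scale
  p80 <- predict_feed_autotrophic(v, ser, 0, 24, 24, scale = 0.8)
  expect_equal(p80$feed_mass_conc, 0.8 * pred$feed_mass_conc,
               tolerance = 1e-9)
  # homogeneous of degree 1 in X0 (via od_to_gdw)
  ser2 <- od_series(c(0, 24), c(1.0, 1.3893), od_to_gdw = 0.8)
  p2 <- predict_feed_autotrophic(v, ser2, 0, 24, 24)
  expect_equal(p2$feed_mass_conc, 2 * pred$feed_mass_conc, tolerance = 1e-9)
  # shrinking culture: floor policy feeds nothing
  shrink <- od_series(c(0, 24), c(2, 1.5))
  p0 <- predict_feed_autotrophic(v, shrink, 0, 24, 24)
  expect_equal(p0$feed_mass_conc, 0)
  expect_true("mu_floor" %in% p0$flags)
})

test_that("feed mass is nondecreasing in the growth rate", {
  v <- build_toy_model(pat5(), "autotrophic")
  masses <- vapply(c(0.001, 0.005, 0.01, 0.02, 0.04), function(mu) {
    ser <- od_series(c(0, 24), c(1, exp(mu * 24)))
    predict_feed_autotrophic(v, ser, 0, 24, 24)$feed_mass_conc
  }, 0)
  expect_true(all(diff(masses) > 0))
})

test_that("heterotrophic prediction handles caps and reduces cleanly", {
  vh <- build_toy_model(ht1(), "heterotrophic")
  ser <- od_series(c(0, 24), c(1.0, 1.3893), od_to_gdw = 0.4)
  mu <- log(1.3893) / 24
  demG <- biomass_demand(ht1())[["C"]] / 6 + 0.5 / 30
  demN <- biomass_demand(ht1())[["N"]]

  preds <- predict_feeds_heterotrophic(vh, ser, 0, 24, 24)
  expect_equal(preds[[1]]$nutrient, "glucose")
  expect_equal(preds[[1]]$uptake_flux, demG * mu, tolerance = 1e-7)
  expect_equal(preds[[2]]$uptake_flux, demN * mu, tolerance = 1e-7)

  # a huge cap leaves the prediction unchanged
  big <- fit_uptake_cap(c(0, 1, 2), c(500, 500, 500) + c(1e-9, 0, -1e-9),
                        degree = 1)
  preds_big <- predict_feeds_heterotrophic(vh, ser, 0, 24, 24, cap = big)
  expect_equal(preds_big[[1]]$feed_mass_conc, preds[[1]]$feed_mass_conc,
               tolerance = 1e-9)
  expect_equal(preds_big[[2]]$feed_mass_conc, preds[[2]]$feed_mass_conc,
               tolerance = 1e-9)

  # a binding cap lowers glucose feed and rescales nitrate to the capped mu
  vcap <- demG * mu / 2
  small <- fit_uptake_cap(c(0, 1, 2), rep(vcap, 3) + c(1e-12, 0, -1e-12),
                          degree = 1)
  preds_cap <- predict_feeds_heterotrophic(vh, ser, 0, 24, 24, cap = small)
  mu_cap <- vcap / demG
  expect_lt(preds_cap[[1]]$feed_mass_conc, preds[[1]]$feed_mass_conc)
  expect_equal(preds_cap[[1]]$mu, mu_cap, tolerance = 1e-7)
  expect_equal(preds_cap[[2]]$uptake_flux, demN * mu_cap, tolerance = 1e-7)
  expect_true("growth_capped" %in% preds_cap[[1]]$flags)
  # autotrophic variants are rejected
  expect_error(predict_feeds_heterotrophic(
    build_toy_model(pat1(), "autotrophic"), ser, 0, 24, 24),
    "heterotrophic")
})

test_that("feasible growth truncates at model capacity", {
  v <- build_toy_model(pat5(), "autotrophic",
                       bounds = list(EX_no3 = c(0, 0.1776)))
  expect_equal(feasible_growth(v, 0.05), 0.05)
  expect_equal(feasible_growth(v, 0.5), 0.1, tolerance = 1e-7)
  dead <- build_toy_model(pat5(), "autotrophic",
                          bounds = list(EX_no3 = c(0, 0)))
  expect_equal(feasible_growth(dead, 0.5), 0, tolerance = 1e-9)
})

test_that("run_schedule iterates predictions and keeps an exact ledger", {
  v <- build_toy_model(pat5(), "autotrophic")
  times <- seq(0, 96, by = 24)
  ser <- od_series(times, exp(0.0137 * times), od_to_gdw = 0.4)
  sched <- run_schedule(v, ser, feed_times = c(24, 48, 72, 96),
                        config = list(horizon = 120))
  expect_equal(nrow(sched$table), 4)
  expect_true(all(is.finite(sched$table$feed_mg_L)))
  # singleton schedule equals the direct prediction
  one <- run_schedule(v, ser, feed_times = 48, config = list(dt = 24))
  direct <- predict_feed_autotrophic(v, ser, 24, 48, 24)
  expect_equal(one$table$feed_mg_L, direct$feed_mass_conc, tolerance = 1e-12)
  # conservation: ledger total is exactly the sum of the schedule
  expect_equal(cumulative_total(sched$ledger, "nitrate"),
               sum(sched$table$feed_mg_L), tolerance = 1e-12)
  # failures at single time points are flagged, not fatal
  sparse <- od_series(c(40, 48), c(1, 1.1))
  part <- run_schedule(v, sparse, feed_times = c(24, 48),
                       config = list(dt = 24))
  expect_equal(part$table$flags[1], "no_observations")
  expect_true(is.finite(part$table$feed_mg_L[2]))
})

test_that("config files round-trip through JSON and YAML", {
  cfg <- list(scale = 0.8, od_to_gdw = 0.4,
              nutrients = list(nitrate = list(mw = 62, rxn = "EX_no3")),
              cap = list(coeffs = c(1, 2, -0.5)))
  jp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jp, auto_unbox = TRUE, digits = NA)
  got <- read_mmc_config(jp)
  expect_equal(got$scale, 0.8)
  expect_equal(got$nutrients[[1]]$name, "nitrate")
  expect_equal(got$nutrients[[1]]$molecular_weight, 62)
  expect_s3_class(got$cap, "uptake_cap_model")
  expect_equal(eval_uptake_cap(got$cap, 1), 2.5)
  yp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yp)
  got2 <- read_mmc_config(yp)
  expect_equal(got2$cap$coeffs, c(1, 2, -0.5))
})
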