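test_that("growth maximization on a linear chain matches hand calculation", {
  net <- chain_model(uptake_ub = 10, yield = 0.5)
  sol <- maximize_growth(net)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5.0, tolerance = 1e-9)
  # shutting the uptake shuts growth
  net0 <- set_bounds(net, "EX_A", ub = 0)
  expect_equal(maximize_growth(net0)$objective_value, 0, tolerance = 1e-9)
})

test_that("LP optimum agrees with exhaustive vertex enumeration", {
  set.seed(7)
  n_checked <- 0
  for (trial in 1:30) {
    net <- random_network()
    j <- sample(length(net$reaction_ids), 1)
    sense <- sample(c("maximize", "minimize"), 1)
    sol <- solve_fba(net, net$reaction_ids[j], sense)
    c_obj <- replace(numeric(length(net$reaction_ids)), j, 1)
    ref <- vertex_lp_optimum(net$S, net$lb, net$ub, c_obj,
                             sense = if (sense == "maximize") "max" else "min")
    expect_equal(sol$status, "optimal")  # 0 is always feasible here
    expect_false(is.na(ref))
    expect_equal(sol$objective_value, ref, tolerance = 1e-7)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 30)
})

test_that("optimal solutions satisfy steady state and bounds", {
  set.seed(11)
  for (trial in 1:20) {
    net <- random_network()
    sol <- maximize_growth(net)
    expect_equal(sol$status, "optimal")
    expect_lt(max(abs(net$S %*% sol$v)), 1e-7)
    expect_true(all(sol$v >= net$lb - 1e-9))
    expect_true(all(sol$v <= net$ub + 1e-9))
  }
})

test_that("uptake minimization at fixed growth returns demand * mu", {
  v <- build_toy_model(pat5(), "autotrophic")  # N demand 1.776 mmol/gDW
  sol <- minimize_uptake_at_growth(v, "nitrate", 0.1)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0.1776, tolerance = 1e-9)
  # no growth, no maintenance: no uptake
  expect_equal(minimize_uptake_at_growth(v, "nitrate", 0)$objective_value, 0,
               tolerance = 1e-9)
  # infeasible when mu exceeds capacity; diagnostic attached
  vlim <- build_toy_model(pat5(), "autotrophic",
                          bounds = list(EX_no3 = c(0, 0.01)))
  bad <- minimize_uptake_at_growth(vlim, "nitrate", 0.1)
  expect_equal(bad$status, "infeasible")
  expect_equal(bad$max_growth, 0.01 / 1.776, tolerance = 1e-7)
})

test_that("a recycled amino-acid pool offsets nitrate demand", {
  # second N source bounded at r: minimized nitrate = max(0, demand*mu - r)
  set.seed(3)
  for (r in c(0, 0.05, 0.2, 1)) {
    v <- build_toy_model(pat5(), "autotrophic", n_recycle = TRUE,
                         bounds = list(EX_nrec = c(0, r)))
    mu <- 0.1
    sol <- minimize_uptake_at_growth(v, "nitrate", mu)
    expect_equal(sol$objective_value, max(0, 1.776 * mu - r),
                 tolerance = 1e-8)
    # cross-check one instance against the vertex oracle
    if (r == 0.05) {
      net <- set_bounds(v$network, "BIOMASS", lb = mu, ub = mu)
      c_obj <- as.numeric(net$reaction_ids == "EX_no3")
      ref <- vertex_lp_optimum(net$S, pmax(net$lb, -1000),
                               pmin(net$ub, 1000), c_obj, "min")
      expect_equal(sol$objective_value, ref, tolerance = 1e-7)
    }
  }
})

test_that("objective-inversion duality holds on the toy model", {
  # growth maximized under uptake bound u, then uptake re-minimized at that
  # growth, must not need more than u
  set.seed(21)
  for (trial in 1:25) {
    u <- stats::runif(1, 0.01, 2)
    v <- build_toy_model(pat5(), "autotrophic",
                         bounds = list(EX_no3 = c(0, u)))
    mu_star <- maximize_growth(v)$objective_value
    v_free <- build_toy_model(pat5(), "autotrophic")
    back <- minimize_uptake_at_growth(v_free, "nitrate", mu_star)
    expect_lte(back$objective_value, u + 1e-7)
  }
})

test_that("minimized uptake is nondecreasing and scales with demand", {
  v <- build_toy_model(pat5(), "autotrophic")
  mus <- seq(0, 0.5, by = 0.05)
  vals <- vapply(mus, function(mu)
    minimize_uptake_at_growth(v, "nitrate", mu)$objective_value, 0)
  expect_true(all(diff(vals) >= -1e-9))
  # linear here: slope equals the demand coefficient
  expect_equal(vals, 1.776 * mus, tolerance = 1e-8)
  # doubling the biomass N coefficient doubles the minimized uptake
  comp2 <- biomass_composition(pat5()$fractions,
                               c(amino_acid = 2 * 11.1), pat5()$c_content)
  v2 <- build_toy_model(comp2, "autotrophic")
  expect_equal(minimize_uptake_at_growth(v2, "nitrate", 0.1)$objective_value,
               2 * 0.1776, tolerance = 1e-8)
})

test_that("lexicographic minimization is stable and consistent", {
  vh <- build_toy_model(ht1(), "heterotrophic")
  mu <- 0.05
  # single-element order reduces to plain minimization
  lex1 <- lexicographic_minimize(vh, mu, order = "nitrate")
  plain <- minimize_uptake_at_growth(vh, "nitrate", mu)
  expect_equal(unname(lex1[["nitrate"]]), plain$objective_value,
               tolerance = 1e-9)
  # mu = 0, no maintenance: all minima zero
  lex0 <- lexicographic_minimize(vh, 0)
  expect_equal(as.numeric(lex0), c(0, 0), tolerance = 1e-9)
  # substitutable carbon: alt source bounded at a
  demC <- biomass_demand(ht1())[["C"]]
  set.seed(5)
  for (a in c(0, 0.1, 0.5, 5)) {
    va <- build_toy_model(ht1(), "heterotrophic", alt_carbon = TRUE,
                          bounds = list(EX_alt = c(0, a)))
    lex <- lexicographic_minimize(va, mu)
    expected_glc <- max(0, demC * mu - 2 * min(a, demC * mu / 2)) / 6 +
      0.5 * mu / 30
    expect_equal(unname(lex[["glucose"]]), expected_glc, tolerance = 1e-7)
    # stage 1 optimum untouched by stage 2: the nitrate-stage solution's
    # glucose flux still equals the stage-1 minimum
    sol2 <- attr(lex, "solutions")[[2]]
    expect_lt(abs(sol2$v[["EX_glc"]] - lex[["glucose"]]), 1e-9)
  }
})
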