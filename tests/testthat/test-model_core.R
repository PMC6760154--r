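test_that("biomass nitrogen demand follows the composition", {
  # 16% amino acid at 11.1 mmol N/g protein, no other N sinks
  comp <- default_composition("PAT5")
  expect_equal(biomass_demand(comp)[["N"]], 0.16 * 11.1, tolerance = 1e-12)

  v <- build_toy_model(comp, "autotrophic")
  bio <- v$network$S[, "BIOMASS"]
  n_coeff <- -sum(bio * v$network$elements[, "N"])
  expect_equal(n_coeff, 1.776, tolerance = 1e-12)

  # reducing amino acid 0.16 -> 0.10 scales the N coefficient by 0.625
  v10 <- set_amino_acid_fraction(v, 0.10)
  expect_equal(biomass_demand(v10$composition)[["N"]] / 1.776, 0.625,
               tolerance = 1e-12)

  # linearity: doubling the protein N content doubles the N demand
  comp2 <- biomass_composition(comp$fractions,
                               n_content = c(amino_acid = 2 * 11.1),
                               c_content = comp$c_content)
  expect_equal(biomass_demand(comp2)[["N"]], 2 * biomass_demand(comp)[["N"]])
})

test_that("composition validation rejects malformed inputs", {
  fr <- default_composition("PAT1")$fractions
  expect_error(biomass_composition(fr * 1.1, c(amino_acid = 11.1), NULL),
               "sum to 1")
  fr_neg <- fr; fr_neg["lipid"] <- -fr_neg["lipid"]
  fr_neg["other"] <- 1 - sum(fr_neg[names(fr_neg) != "other"])
  expect_error(biomass_composition(fr_neg, c(amino_acid = 11.1), NULL),
               "non-negative")
  expect_error(build_toy_model(default_composition("PAT1"), "mixotrophic"))
})

test_that("amino-acid editing renormalizes and is involutive", {
  v <- build_toy_model(pat5(), "autotrophic")
  v10 <- set_amino_acid_fraction(v, 0.10)
  # non-AA fractions scale by (1-0.10)/(1-0.16)
  scale <- (1 - 0.10) / (1 - 0.16)
  expect_equal(v10$composition$fractions[["lipid"]],
               0.48 * scale, tolerance = 1e-12)
  expect_equal(sum(v10$composition$fractions), 1, tolerance = 1e-12)
  # identity edit
  vsame <- set_amino_acid_fraction(v, 0.16)
  expect_equal(vsame$composition$fractions, v$composition$fractions,
               tolerance = 1e-12)
  # involution: 0.16 -> 0.02 -> 0.16 recovers the original
  back <- set_amino_acid_fraction(set_amino_acid_fraction(v, 0.02), 0.16)
  expect_equal(back$composition$fractions, v$composition$fractions,
               tolerance = 1e-9)
  # original untouched
  expect_equal(v$composition$fractions[["amino_acid"]], 0.16)
  expect_error(set_amino_acid_fraction(v, 1.2), "between 0 and 1")
})

test_that("mass balance validation passes built toys and flags perturbations", {
  set.seed(42)
  for (i in 1:20) {
    comp <- random_composition()
    mode <- if (i %% 2 == 0) "autotrophic" else "heterotrophic"
    v <- build_toy_model(comp, mode)
    rep <- validate_mass_balance(v$network)
    expect_true(rep$pass)
  }

  v <- build_toy_model(pat1(), "autotrophic")
  v$network$S["Nunit", "N_assim"] <- v$network$S["Nunit", "N_assim"] + 0.1
  rep <- validate_mass_balance(v$network)
  expect_false(rep$pass)
  bad <- rep$residuals[abs(rep$residuals$residual) > 1e-9, ]
  expect_equal(unique(bad$reaction), "N_assim")
  expect_equal(abs(bad$residual), 0.1, tolerance = 1e-12)

  # empty network: vacuous pass
  empty <- metabolic_network(character(), character(),
                             matrix(0, 0, 0), numeric(), numeric(),
                             biomass_rxn = character())
  expect_true(validate_mass_balance(empty)$pass)
})

test_that("trophic modes gate the carbon/energy sources", {
  va <- build_toy_model(pat1(), "autotrophic")
  expect_equal(va$network$ub[["EX_glc"]], 0)
  vh <- build_toy_model(ht1(), "heterotrophic")
  expect_equal(vh$network$ub[["EX_photon"]], 0)
  # no carbon/energy source at all: growth collapses to zero
  dark <- build_toy_model(pat1(), "autotrophic",
                          bounds = list(EX_photon = c(0, 0)))
  sol <- maximize_growth(dark)
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("JSON model dialect round-trips", {
  v <- build_toy_model(pat5(), "heterotrophic", alt_carbon = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(v, path)
  v2 <- model_from_json(path)
  expect_equal(v2$network$S, v$network$S)
  expect_equal(v2$network$lb, v$network$lb)
  expect_equal(v2$network$ub, v$network$ub)
  expect_equal(v2$network$uptake_rxns, v$network$uptake_rxns)
  expect_equal(v2$composition$fractions, v$composition$fractions)
  expect_equal(v2$trophic_mode, "heterotrophic")
})

test_that("network invariants are enforced", {
  expect_error(metabolic_network("A", c("r1", "r2"),
                                 matrix(c(1, -1), 1, 2), lb = c(0, 5),
                                 ub = c(10, 2), biomass_rxn = "r2"),
               "lb > ub.*r2")
  expect_error(metabolic_network("A", "r1", matrix(1, 1, 1), 0, 1,
                                 biomass_rxn = "nope"),
               "not in reaction_ids")
  expect_error(metabolic_network("A", "r1", matrix(1, 1, 1), 0, 1,
                                 biomass_rxn = "r1",
                                 uptake_rxns = c(x = "missing")),
               "not in network")
})
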