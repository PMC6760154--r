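# Small fixture builders shared across test files. Everything is generated
# in code; no stored fixtures.

# Linear chain: nutrient uptake (ub = uptake_ub) feeding a biomass reaction
# that consumes 1/yield units of A per unit growth.
chain_model <- function(uptake_ub = 10, yield = 0.5) {
  metabolic_network(
    metabolite_ids = "A",
    reaction_ids = c("EX_A", "BIO"),
    S = matrix(c(1, -1 / yield), nrow = 1,
               dimnames = list("A", c("EX_A", "BIO"))),
    lb = c(0, 0), ub = c(uptake_ub, 1000),
    biomass_rxn = "BIO", uptake_rxns = c(a = "EX_A"))
}

# Random small network with 0 always feasible (lb <= 0 <= ub).
random_network <- function(n_mets = NULL, n_rxns = NULL) {
  m <- n_mets %||% sample(1:4, 1)
  n <- n_rxns %||% sample(2:6, 1)
  S <- matrix(sample(c(-2, -1, -1, 0, 0, 1, 1, 2), m * n, replace = TRUE),
              m, n, dimnames = list(paste0("m", seq_len(m)),
                                    paste0("r", seq_len(n))))
  lb <- ifelse(stats::runif(n) < 0.5, 0, -round(stats::runif(n, 0, 3), 2))
  ub <- round(stats::runif(n, 0.5, 5), 2)
  metabolic_network(rownames(S), colnames(S), S, lb, ub,
                    biomass_rxn = colnames(S)[n])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random valid composition (fractions normalized, positive contents).
random_composition <- function() {
  fr <- stats::runif(6, 0.02, 1)
  fr <- fr / sum(fr)
  names(fr) <- c("amino_acid", "carbohydrate", "lipid", "chlorophyll",
                 "nucleotide", "other")
  biomass_composition(
    fr,
    n_content = c(amino_acid = stats::runif(1, 5, 15)),
    c_content = stats::setNames(stats::runif(6, 10, 70), names(fr)))
}

pat1 <- function() default_composition("PAT1")
pat5 <- function() default_composition("PAT5")
ht1 <- function() default_composition("HT1")
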