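# Constraint-based model containers: stoichiometry, bounds, biomass composition,
# and the parameterized toy network whose biomass column is rebuilt from a
# macromolecular composition vector.

MACROMOLECULES <- c("amino_acid", "carbohydrate", "lipid", "chlorophyll",
                    "nucleotide", "other")

#' Biomass macromolecular composition
#'
#' A composition assigns each macromolecule class a mass fraction of dry
#' biomass together with its nitrogen and carbon content. The biomass
#' pseudo-reaction of the toy network consumes one gram of each class per
#' `fractions[m]` gram dry weight, so the nitrogen demand of growth is
#' `sum(fractions * n_content)` mmol N per gDW and likewise for carbon.
#'
#' @param fractions named numeric, mass fractions (must sum to 1 within 1e-9).
#'   Names must cover amino_acid, carbohydrate, lipid, chlorophyll,
#'   nucleotide, other.
#' @param n_content named numeric, mmol nitrogen per gram of each class.
#' @param c_content named numeric, mmol carbon per gram of each class.
#' @return an object of class `biomass_composition`.
#' @export
biomass_composition <- function(fractions, n_content, c_content) {
  fractions <- fractions[MACROMOLECULES]
  if (anyNA(fractions)) {
    stop("fractions must be named and cover: ",
         paste(MACROMOLECULES, collapse = ", "))
  }
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 within 1e-9 (got ",
         format(sum(fractions), digits = 12), ")")
  }
  n_content <- fill_content(n_content)
  c_content <- fill_content(c_content)
  if (any(n_content < 0) || any(c_content < 0)) {
    stop("n_content and c_content must be non-negative")
  }
  structure(list(fractions = fractions, n_content = n_content,
                 c_content = c_content),
            class = "biomass_composition")
}

fill_content <- function(x) {
  out <- stats::setNames(numeric(length(MACROMOLECULES)), MACROMOLECULES)
  if (!is.null(x)) {
    bad <- setdiff(names(x), MACROMOLECULES)
    if (length(bad)) stop("unknown macromolecule(s): ", paste(bad, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

#' Built-in biomass composition presets
#'
#' Placeholder compositions for a nitrogen-replete autotrophic cell
#' (`"PAT1"`-like), a nitrogen-replete heterotrophic cell (`"HT1"`-like) and a
#' nitrogen-starved autotrophic cell (`"PAT5"`-like, 16% amino acid). The
#' amino-acid fraction of the starved preset is the only literature-anchored
#' number; the remaining fractions are configuration defaults, not
#' measurements. All cellular nitrogen is bookkept in the amino-acid pool
#' (11.1 mmol N/g protein, i.e. ~16% N by mass), so nitrate demand scales
#' directly with the amino-acid fraction.
#'
#' @param kind one of `"PAT1"`, `"HT1"`, `"PAT5"`.
#' @return a [biomass_composition()].
#' @export
default_composition <- function(kind = c("PAT1", "HT1", "PAT5")) {
  kind <- match.arg(kind)
  fr <- switch(kind,
    PAT1 = c(amino_acid = 0.45, carbohydrate = 0.25, lipid = 0.20,
             chlorophyll = 0.02, nucleotide = 0.05, other = 0.03),
    HT1  = c(amino_acid = 0.40, carbohydrate = 0.30, lipid = 0.22,
             chlorophyll = 0.005, nucleotide = 0.05, other = 0.025),
    PAT5 = c(amino_acid = 0.16, carbohydrate = 0.25, lipid = 0.48,
             chlorophyll = 0.01, nucleotide = 0.04, other = 0.06))
  biomass_composition(
    fractions = fr,
    n_content = c(amino_acid = 11.1),
    c_content = c(amino_acid = 41.7, carbohydrate = 37.0, lipid = 63.0,
                  chlorophyll = 61.6, nucleotide = 29.5, other = 30.0))
}

#' Nitrogen and carbon demand of a composition
#'
#' @param composition a [biomass_composition()].
#' @return named numeric with elements `N` and `C`, mmol per gDW.
#' @export
biomass_demand <- function(composition) {
  stopifnot(inherits(composition, "biomass_composition"))
  c(N = sum(composition$fractions * composition$n_content),
    C = sum(composition$fractions * composition$c_content))
}

#' Metabolic network container
#'
#' Thin validated container for a stoichiometric model: matrix `S`
#' (metabolites x reactions, mmol per unit flux), flux bounds, a tagged
#' biomass reaction and a nutrient-name to uptake-reaction map. An optional
#' `elements` matrix (metabolites x bookkeeping elements) drives
#' [validate_mass_balance()].
#'
#' @param metabolite_ids,reaction_ids character identifiers.
#' @param S numeric matrix, rows metabolites, columns reactions.
#' @param lb,ub numeric per-reaction flux bounds (mmol/gDW/h; biomass 1/h).
#' @param biomass_rxn identifier of the biomass pseudo-reaction.
#' @param uptake_rxns named character, nutrient name -> reaction id.
#' @param elements optional numeric matrix (metabolites x elements).
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolite_ids, reaction_ids, S, lb, ub,
                              biomass_rxn, uptake_rxns = character(),
                              elements = NULL) {
  S <- as.matrix(S)
  if (nrow(S) != length(metabolite_ids) || ncol(S) != length(reaction_ids)) {
    stop("S must be length(metabolite_ids) x length(reaction_ids)")
  }
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  lb <- stats::setNames(as.numeric(lb), reaction_ids)
  ub <- stats::setNames(as.numeric(ub), reaction_ids)
  bad <- which(lb > ub + 1e-12)
  if (length(bad)) {
    stop("lb > ub for reaction(s): ", paste(reaction_ids[bad], collapse = ", "))
  }
  if (length(reaction_ids) && !biomass_rxn %in% reaction_ids) {
    stop("biomass reaction '", biomass_rxn, "' not in reaction_ids")
  }
  miss <- setdiff(unname(uptake_rxns), reaction_ids)
  if (length(miss)) {
    stop("uptake reaction(s) not in network: ", paste(miss, collapse = ", "))
  }
  if (!is.null(elements)) {
    elements <- as.matrix(elements)
    stopifnot(nrow(elements) == length(metabolite_ids))
    rownames(elements) <- metabolite_ids
  }
  structure(list(metabolite_ids = metabolite_ids,
                 reaction_ids = reaction_ids,
                 S = S, lb = lb, ub = ub,
                 biomass_rxn = biomass_rxn,
                 uptake_rxns = uptake_rxns,
                 elements = elements),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions\n", sep = "")
  cat("  biomass: ", x$biomass_rxn, "\n", sep = "")
  if (length(x$uptake_rxns)) {
    cat("  uptakes: ",
        paste(names(x$uptake_rxns), x$uptake_rxns, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Set flux bounds on a network (returns a modified copy)
#'
#' @param network a [metabolic_network()].
#' @param rxn reaction identifier.
#' @param lb,ub new bounds; `NULL` leaves the bound unchanged.
#' @return the modified network.
#' @export
set_bounds <- function(network, rxn, lb = NULL, ub = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  if (!rxn %in% network$reaction_ids) stop("unknown reaction: ", rxn)
  if (!is.null(lb)) network$lb[rxn] <- lb
  if (!is.null(ub)) network$ub[rxn] <- ub
  if (network$lb[rxn] > network$ub[rxn] + 1e-12) {
    stop("lb > ub for reaction ", rxn)
  }
  network
}

#' Model variant: network + composition + trophic mode
#'
#' @param name label, e.g. `"PAT1-like"`.
#' @param network a [metabolic_network()].
#' @param composition a [biomass_composition()] (may be `NULL` for
#'   SBML-loaded models whose biomass stoichiometry is opaque).
#' @param trophic_mode `"autotrophic"` or `"heterotrophic"`.
#' @param builder_args internal; arguments needed to rebuild a toy network.
#' @return an object of class `model_variant`.
#' @export
model_variant <- function(name, network, composition = NULL,
                          trophic_mode = c("autotrophic", "heterotrophic"),
                          builder_args = NULL) {
  trophic_mode <- match.arg(trophic_mode)
  stopifnot(inherits(network, "metabolic_network"))
  structure(list(name = name, network = network, composition = composition,
                 trophic_mode = trophic_mode, builder_args = builder_args),
            class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant> ", x$name, " (", x$trophic_mode, ")\n", sep = "")
  print(x$network)
  invisible(x)
}

#' Build the parameterized toy metabolic model
#'
#' A desk-scale constraint-based network standing in for a genome-scale algal
#' model. Nutrient uptakes (nitrate, glucose, photon, CO2), abstract N-unit /
#' C-unit assimilation, an ATP energy pseudo-metabolite, one synthesis
#' reaction per macromolecule class and a biomass reaction whose coefficients
#' are the composition mass fractions. The biomass column therefore demands
#' `sum(fractions * n_content)` mmol N and `sum(fractions * c_content)` mmol C
#' per gDW, which is exactly what the feed controller reads off the model.
#'
#' Carbon fixation consumes photons directly (2 photons per C-unit), so
#' heterotrophic variants (photon bound 0) must route all carbon and energy
#' through glucose; glucose respiration yields 30 ATP and releases its 6
#' carbons as CO2.
#'
#' @param composition a [biomass_composition()].
#' @param trophic_mode `"autotrophic"` (glucose uptake bound to 0) or
#'   `"heterotrophic"` (photon uptake bound to 0).
#' @param bounds named list of length-2 numeric vectors overriding default
#'   bounds per reaction id, e.g. `list(EX_no3 = c(0, 5))`.
#' @param alt_carbon if `TRUE`, add an alternative carbon source (2 C-units
#'   per mmol) with uptake reaction `EX_alt`, registered as nutrient
#'   `alt_carbon`.
#' @param n_recycle if `TRUE`, add a direct N-unit source `EX_nrec`
#'   (a recycled amino-acid pool), registered as nutrient `n_recycle`.
#' @param syn_atp ATP cost per gram macromolecule synthesized (default 0.5).
#' @param maintenance non-growth-associated ATP drain lower bound
#'   (mmol/gDW/h, default 0).
#' @param name variant label.
#' @return a [model_variant()].
#' @export
build_toy_model <- function(composition,
                            trophic_mode = c("autotrophic", "heterotrophic"),
                            bounds = list(),
                            alt_carbon = FALSE, n_recycle = FALSE,
                            syn_atp = 0.5, maintenance = 0,
                            name = NULL) {
  trophic_mode <- match.arg(trophic_mode)
  stopifnot(inherits(composition, "biomass_composition"))

  mets <- c("no3", "glc", "photon", "co2", "Nunit", "Cunit", "atp",
            paste0("MM_", MACROMOLECULES))
  if (alt_carbon) mets <- c(mets, "altc")

  # element bookkeeping: mmol N / mmol C carried per unit of each metabolite
  elements <- matrix(0, nrow = length(mets), ncol = 2,
                     dimnames = list(mets, c("N", "C")))
  elements["no3", "N"] <- 1
  elements["glc", "C"] <- 6
  elements["co2", "C"] <- 1
  elements["Nunit", "N"] <- 1
  elements["Cunit", "C"] <- 1
  for (m in MACROMOLECULES) {
    elements[paste0("MM_", m), "N"] <- composition$n_content[m]
    elements[paste0("MM_", m), "C"] <- composition$c_content[m]
  }
  if (alt_carbon) elements["altc", "C"] <- 2

  rxn <- function(stoich) {
    v <- stats::setNames(numeric(length(mets)), mets)
    v[names(stoich)] <- stoich
    v
  }
  cols <- list(
    EX_no3    = rxn(c(no3 = 1)),
    EX_glc    = rxn(c(glc = 1)),
    EX_photon = rxn(c(photon = 1)),
    EX_co2    = rxn(c(co2 = 1)),
    N_assim   = rxn(c(no3 = -1, Nunit = 1)),
    C_fix     = rxn(c(co2 = -1, photon = -2, Cunit = 1)),
    GLC_C     = rxn(c(glc = -1, Cunit = 6)),
    GLC_ATP   = rxn(c(glc = -1, atp = 30, co2 = 6)),
    PHO_ATP   = rxn(c(photon = -1, atp = 1)),
    ATP_maint = rxn(c(atp = -1)))
  for (m in MACROMOLECULES) {
    st <- c(-composition$n_content[[m]], -composition$c_content[[m]],
            -syn_atp, 1)
    names(st) <- c("Nunit", "Cunit", "atp", paste0("MM_", m))
    cols[[paste0("SYN_", m)]] <- rxn(st)
  }
  bio <- stats::setNames(-composition$fractions, paste0("MM_", MACROMOLECULES))
  cols[["BIOMASS"]] <- rxn(bio)
  if (n_recycle) cols[["EX_nrec"]] <- rxn(c(Nunit = 1))
  if (alt_carbon) {
    cols[["EX_alt"]] <- rxn(c(altc = 1))
    cols[["ALT_C"]] <- rxn(c(altc = -1, Cunit = 2))
  }

  S <- do.call(cbind, cols)
  rids <- names(cols)
  lb <- stats::setNames(rep(0, length(rids)), rids)
  ub <- stats::setNames(rep(1000, length(rids)), rids)
  lb["EX_co2"] <- -1000          # CO2 may be secreted (respiration)
  lb["ATP_maint"] <- maintenance
  if (trophic_mode == "autotrophic") ub["EX_glc"] <- 0 else ub["EX_photon"] <- 0

  for (r in names(bounds)) {
    if (!r %in% rids) stop("bound override for unknown reaction: ", r)
    lb[r] <- bounds[[r]][1]
    ub[r] <- bounds[[r]][2]
  }

  uptakes <- c(nitrate = "EX_no3", glucose = "EX_glc",
               photon = "EX_photon", co2 = "EX_co2")
  if (n_recycle) uptakes <- c(uptakes, n_recycle = "EX_nrec")
  if (alt_carbon) uptakes <- c(uptakes, alt_carbon = "EX_alt")

  net <- metabolic_network(mets, rids, S, lb, ub,
                           biomass_rxn = "BIOMASS", uptake_rxns = uptakes,
                           elements = elements)
  model_variant(
    name = name %||% paste0("toy-", trophic_mode),
    network = net, composition = composition, trophic_mode = trophic_mode,
    builder_args = list(bounds = bounds, alt_carbon = alt_carbon,
                        n_recycle = n_recycle, syn_atp = syn_atp,
                        maintenance = maintenance))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Edit the amino-acid mass fraction of a model variant
#'
#' Sets `fractions["amino_acid"]` to `target_aa` and rescales every other
#' fraction by `(1 - target_aa) / (1 - old_aa)` so the composition stays
#' normalized to 1, then rebuilds the biomass reaction. This is the
#' composition edit used to derive reduced-protein model variants (e.g. 16%
#' to 10% or 2% amino acid) for nitrogen-limited feeding.
#'
#' @param variant a toy [model_variant()].
#' @param target_aa new amino-acid mass fraction, in (0, 1).
#' @param name optional new variant label.
#' @return a new [model_variant()]; the input is unmodified.
#' @export
set_amino_acid_fraction <- function(variant, target_aa, name = NULL) {
  stopifnot(inherits(variant, "model_variant"))
  if (!is.numeric(target_aa) || target_aa <= 0 || target_aa >= 1) {
    stop("target_aa must lie strictly between 0 and 1")
  }
  comp <- variant$composition
  if (is.null(comp)) {
    stop("variant has no composition (SBML-loaded models cannot be re-edited)")
  }
  old_aa <- comp$fractions[["amino_acid"]]
  if (old_aa >= 1) stop("amino-acid fraction is already 1; cannot rescale others")
  fr <- comp$fractions
  scale <- (1 - target_aa) / (1 - old_aa)
  fr[setdiff(MACROMOLECULES, "amino_acid")] <-
    fr[setdiff(MACROMOLECULES, "amino_acid")] * scale
  fr["amino_acid"] <- target_aa
  fr <- fr / sum(fr)   # guard round-off; change is < 1e-15
  newcomp <- biomass_composition(fr, comp$n_content, comp$c_content)
  if (is.null(variant$builder_args)) {
    stop("variant was not produced by build_toy_model; cannot rebuild")
  }
  ba <- variant$builder_args
  build_toy_model(newcomp, variant$trophic_mode, bounds = ba$bounds,
                  alt_carbon = ba$alt_carbon, n_recycle = ba$n_recycle,
                  syn_atp = ba$syn_atp, maintenance = ba$maintenance,
                  name = name %||% sprintf("%s-%g%%AA", variant$name,
                                           100 * target_aa))
}

#' Check elemental mass balance of internal reactions
#'
#' Computes, for every reaction column, the net amount of each bookkeeping
#' element (`t(elements) %*% S`). Exchange reactions (single-metabolite
#' columns and registered uptakes) and the biomass reaction exchange mass
#' with the environment and are exempted. The network passes when the largest
#' internal residual is below `tol`.
#'
#' @param network a [metabolic_network()].
#' @param tol residual tolerance (default 1e-6).
#' @return a list with `pass`, `residuals` (data.frame reaction/element/
#'   residual for internal reactions), `exempt` (character), `max_residual`.
#' @export
validate_mass_balance <- function(network, tol = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"))
  n <- length(network$reaction_ids)
  if (n == 0) {
    return(list(pass = TRUE,
                residuals = data.frame(reaction = character(),
                                       element = character(),
                                       residual = numeric()),
                exempt = character(), max_residual = 0))
  }
  exch <- network$reaction_ids[colSums(network$S != 0) <= 1]
  exempt <- union(union(exch, unname(network$uptake_rxns)),
                  network$biomass_rxn)
  internal <- setdiff(network$reaction_ids, exempt)
  if (is.null(network$elements) || !length(internal)) {
    return(list(pass = TRUE,
                residuals = data.frame(reaction = character(),
                                       element = character(),
                                       residual = numeric()),
                exempt = exempt, max_residual = 0))
  }
  R <- t(network$elements) %*% network$S[, internal, drop = FALSE]
  df <- data.frame(
    reaction = rep(colnames(R), each = nrow(R)),
    element = rep(rownames(R), times = ncol(R)),
    residual = as.vector(R))
  mx <- max(abs(df$residual))
  list(pass = mx < tol, residuals = df, exempt = exempt, max_residual = mx)
}

#' Serialize a model variant to the JSON model dialect
#'
#' Dialect: `{metabolites: [], reactions: [{id, stoich: {met: coeff}, lb, ub}],
#' biomass: id, uptakes: {}}`. Compositions and element bookkeeping round-trip
#' through extra top-level fields when present.
#'
#' @param variant a [model_variant()].
#' @param path output file; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
model_to_json <- function(variant, path = NULL) {
  stopifnot(inherits(variant, "model_variant"))
  net <- variant$network
  rxns <- lapply(net$reaction_ids, function(r) {
    col <- net$S[, r]
    nz <- col[col != 0]
    list(id = r, stoich = as.list(nz), lb = net$lb[[r]], ub = net$ub[[r]])
  })
  obj <- list(metabolites = net$metabolite_ids,
              reactions = rxns,
              biomass = net$biomass_rxn,
              uptakes = as.list(net$uptake_rxns),
              trophic_mode = variant$trophic_mode,
              name = variant$name)
  if (!is.null(variant$composition)) {
    obj$composition <- lapply(unclass(variant$composition), as.list)
  }
  if (!is.null(net$elements)) {
    obj$elements <- apply(net$elements, 1, as.list, simplify = FALSE)
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read a model variant from the JSON model dialect
#'
#' @param path file path or JSON string.
#' @return a [model_variant()].
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- unlist(obj$metabolites)
  rids <- vapply(obj$reactions, `[[`, "", "id")
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lb <- ub <- stats::setNames(numeric(length(rids)), rids)
  for (r in obj$reactions) {
    st <- unlist(r$stoich)
    S[names(st), r$id] <- st
    lb[r$id] <- r$lb
    ub[r$id] <- r$ub
  }
  elements <- NULL
  if (!is.null(obj$elements)) {
    enames <- names(obj$elements[[1]])
    elements <- do.call(rbind, lapply(obj$elements, unlist))
    rownames(elements) <- mets
    colnames(elements) <- enames
  }
  net <- metabolic_network(mets, rids, S, lb, ub,
                           biomass_rxn = obj$biomass,
                           uptake_rxns = unlist(obj$uptakes),
                           elements = elements)
  comp <- NULL
  if (!is.null(obj$composition)) {
    comp <- biomass_composition(unlist(obj$composition$fractions),
                                unlist(obj$composition$n_content),
                                unlist(obj$composition$c_content))
  }
  model_variant(name = obj$name %||% "json-model", network = net,
                composition = comp,
                trophic_mode = obj$trophic_mode %||% "autotrophic")
}
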