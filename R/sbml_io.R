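# Minimal SBML import/export for constraint-based models. Covers the subset
# genome-scale algal models actually use: species, reactions with reactant/
# product stoichiometries, FBC v2 flux bounds and objectives, with a fallback
# to legacy KINETIC_LAW-encoded LOWER_BOUND/UPPER_BOUND parameters. Parsing
# is namespace-agnostic (local-name() XPath) to tolerate dialect drift.

#' Load a constraint-based model from SBML
#'
#' Reads an SBML Level 2/3 file into a [model_variant()]. Flux bounds are
#' taken from FBC v2 attributes when present, otherwise from kineticLaw
#' parameters named `LOWER_BOUND` / `UPPER_BOUND` (default +/-1000 when
#' absent). The biomass reaction is auto-detected from the active FBC
#' objective, else by case-insensitive id/name match on "biomass"; both are
#' overridable.
#'
#' @param path SBML file path.
#' @param biomass_rxn optional explicit biomass reaction id.
#' @param uptake_map named character mapping nutrient names to uptake
#'   reaction ids (e.g. `c(nitrate = "EX_no3_e")`); entries absent from the
#'   model raise an error.
#' @param trophic_mode recorded on the variant (default autotrophic).
#' @return a [model_variant()] with `composition = NULL`.
#' @export
load_sbml <- function(path, biomass_rxn = NULL, uptake_map = character(),
                      trophic_mode = "autotrophic") {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- xml2::read_xml(path)

  species <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% c("true", "1")
  if (!length(mets)) stop("no species found in ", path)

  params <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rnodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rnodes)) stop("no reactions found in ", path)
  rids <- xml2::xml_attr(rnodes, "id")

  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  lb <- stats::setNames(rep(-1000, length(rids)), rids)
  ub <- stats::setNames(rep(1000, length(rids)), rids)

  for (i in seq_along(rnodes)) {
    node <- rnodes[[i]]
    for (ref in xml2::xml_find_all(node, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      sp <- xml2::xml_attr(ref, "species")
      st <- xml2::xml_attr(ref, "stoichiometry")
      if (sp %in% mets) S[sp, i] <- S[sp, i] - as.numeric(st %||% "1")
    }
    for (ref in xml2::xml_find_all(node, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      sp <- xml2::xml_attr(ref, "species")
      st <- xml2::xml_attr(ref, "stoichiometry")
      if (sp %in% mets) S[sp, i] <- S[sp, i] + as.numeric(st %||% "1")
    }
    rev <- xml2::xml_attr(node, "reversible") %||% "true"
    if (rev %in% c("false", "0")) lb[i] <- 0

    # FBC v2 bound attributes referencing global parameters
    fbc_lo <- attr_any_ns(node, "lowerFluxBound")
    fbc_up <- attr_any_ns(node, "upperFluxBound")
    if (!is.na(fbc_lo) && fbc_lo %in% names(pvals)) lb[i] <- pvals[[fbc_lo]]
    if (!is.na(fbc_up) && fbc_up %in% names(pvals)) ub[i] <- pvals[[fbc_up]]

    # legacy kineticLaw-encoded bounds
    for (kp in xml2::xml_find_all(node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter' or local-name()='localParameter']")) {
      pid <- xml2::xml_attr(kp, "id")
      val <- as.numeric(xml2::xml_attr(kp, "value"))
      if (identical(pid, "LOWER_BOUND")) lb[i] <- val
      if (identical(pid, "UPPER_BOUND")) ub[i] <- val
    }
  }

  bad <- which(lb > ub + 1e-12)
  if (length(bad)) {
    stop("invalid bounds (lb > ub) for reaction(s): ",
         paste(rids[bad], collapse = ", "))
  }

  if (is.null(biomass_rxn)) {
    obj <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
    cand <- unique(stats::na.omit(c(attr_any_ns_all(obj, "reaction"))))
    if (!length(cand)) {
      hits <- grepl("biomass", rids, ignore.case = TRUE)
      nm <- xml2::xml_attr(rnodes, "name")
      hits <- hits | (!is.na(nm) & grepl("biomass", nm, ignore.case = TRUE))
      cand <- rids[hits]
    }
    if (!length(cand)) {
      stop("no biomass reaction candidate found; pass biomass_rxn explicitly")
    }
    if (length(cand) > 1) {
      stop("ambiguous biomass reaction, candidates: ",
           paste(cand, collapse = ", "), "; pass biomass_rxn explicitly")
    }
    biomass_rxn <- cand
  }
  if (!biomass_rxn %in% rids) stop("biomass reaction not in model: ", biomass_rxn)

  miss <- setdiff(unname(uptake_map), rids)
  if (length(miss)) {
    stop("uptake reaction(s) not in model: ", paste(miss, collapse = ", "))
  }

  keep <- !boundary
  net <- metabolic_network(mets[keep], rids, S[keep, , drop = FALSE],
                           lb, ub, biomass_rxn = biomass_rxn,
                           uptake_rxns = uptake_map)
  model_variant(name = tools::file_path_sans_ext(basename(path)),
                network = net, composition = NULL,
                trophic_mode = trophic_mode)
}

attr_any_ns <- function(node, name) {
  attrs <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(attrs))
  if (length(hit)) attrs[[hit[1]]] else NA_character_
}

attr_any_ns_all <- function(nodes, name) {
  vapply(nodes, attr_any_ns, "", name = name)
}

#' Write a model variant to SBML Level 3 with FBC v2
#'
#' Emits species, reactions with stoichiometries, per-reaction FBC bound
#' parameters and an active maximization objective on the biomass reaction —
#' enough to round-trip through [load_sbml()].
#'
#' @param variant a [model_variant()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_sbml <- function(variant, path) {
  stopifnot(inherits(variant, "model_variant"))
  net <- variant$network
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(variant$name)),
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '    <listOfSpecies>')
  for (m in net$metabolite_ids) {
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m)))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  for (r in net$reaction_ids) {
    lines <- c(lines,
      sprintf('      <parameter id="%s_lb" value="%.17g" constant="true"/>', esc(r), net$lb[[r]]),
      sprintf('      <parameter id="%s_ub" value="%.17g" constant="true"/>', esc(r), net$ub[[r]]))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (r in net$reaction_ids) {
    col <- net$S[, r]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s_lb" fbc:upperFluxBound="%s_ub">',
      esc(r), if (net$lb[[r]] < 0) "true" else "false", esc(r), esc(r)))
    reac <- names(col)[col < 0]
    prod <- names(col)[col > 0]
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>',
        sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                esc(reac), -col[reac]),
        '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>',
        sprintf('          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
                esc(prod), col[prod]),
        '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            esc(net$biomass_rxn)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
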