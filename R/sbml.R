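#' Export the elementary reaction network as SBML Level 3
#'
#' Writes the full mass-action scheme (promoter binding/release, ternary
#' complex formation, production, degradation) of either model as an SBML
#' Level 3 Version 2 document, with each reversible binding pair realized as
#' forward rate `rate_scale * K` and reverse rate `rate_scale`. Intended for
#' interoperability with pathway tools; no SBML import is provided.
#'
#' @param p A [model1_params()] or [model2_params()] object.
#' @param path Output file path (`.xml`).
#' @param rate_scale Binding/release rate multiplier (timescale separation).
#' @return `path`, invisibly.
#' @export
export_sbml <- function(p, path, rate_scale = 1) {
  stopifnot(inherits(p, "kinetic_params"))
  check_positive_scalar(rate_scale, "rate_scale")
  model1 <- !inherits(p, "model2_params")
  K3 <- ternary_K(p)

  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2"
  )
  model <- xml2::xml_add_child(
    doc, "model",
    id = if (model1) "independent_binding_circuit" else "ternary_complex_circuit",
    substanceUnits = "dimensionless", timeUnits = "dimensionless"
  )
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")

  init <- full_network_state(p, X = 0, Y = 0, promoters = "free")
  species <- xml2::xml_add_child(model, "listOfSpecies")
  for (sp in full_species) {
    xml2::xml_add_child(species, "species", id = sp, compartment = "cell",
                        initialConcentration = format(init[[sp]]),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  params <- xml2::xml_add_child(model, "listOfParameters")
  rates <- c(
    kon_xX = rate_scale * p$K_x, kon_xY = rate_scale * p$K_yx,
    kon_xXY = rate_scale * K3[["x"]],
    kon_yY = rate_scale * p$K_y, kon_yX = rate_scale * p$K_xy,
    kon_yYX = rate_scale * K3[["y"]],
    koff = rate_scale,
    alpha_x = p$alpha_x, alpha_y = p$alpha_y,
    delta_x = p$delta_x, delta_y = p$delta_y
  )
  for (nm in names(rates)) {
    xml2::xml_add_child(params, "parameter", id = nm,
                        value = format(rates[[nm]]), constant = "true")
  }

  reactions <- xml2::xml_add_child(model, "listOfReactions")
  add_rxn <- function(id, reactants, products, rate_terms) {
    rx <- xml2::xml_add_child(reactions, "reaction", id = id,
                              reversible = "false")
    if (length(reactants) > 0) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (sp in reactants) {
        xml2::xml_add_child(lr, "speciesReference", species = sp,
                            stoichiometry = "1", constant = "true")
      }
    }
    if (length(products) > 0) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (sp in products) {
        xml2::xml_add_child(lp, "speciesReference", species = sp,
                            stoichiometry = "1", constant = "true")
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    if (length(rate_terms) == 1L) {
      xml2::xml_add_child(math, "ci", rate_terms)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (term in rate_terms) xml2::xml_add_child(ap, "ci", term)
    }
  }
  bind_pair <- function(stub, A, B, AB, kon) {
    add_rxn(paste0(stub, "_bind"), c(A, B), AB, c(kon, A, B))
    add_rxn(paste0(stub, "_release"), AB, c(A, B), c("koff", AB))
  }
  bind_pair("xX", "x", "X", "xX", "kon_xX")
  bind_pair("xY", "x", "Y", "xY", "kon_xY")
  bind_pair("xXY", "xX", "Y", "xXY", "kon_xXY")
  if (model1) bind_pair("xXY_alt", "xY", "X", "xXY", "kon_xX")
  bind_pair("yY", "y", "Y", "yY", "kon_yY")
  bind_pair("yX", "y", "X", "yX", "kon_yX")
  bind_pair("yYX", "yY", "X", "yYX", "kon_yYX")
  if (model1) bind_pair("yYX_alt", "yX", "Y", "yYX", "kon_yY")
  add_rxn("produce_X", "xX", c("xX", "X"), c("alpha_x", "xX"))
  add_rxn("produce_Y", "yY", c("yY", "Y"), c("alpha_y", "yY"))
  add_rxn("degrade_X", "X", character(), c("delta_x", "X"))
  add_rxn("degrade_Y", "Y", character(), c("delta_y", "Y"))

  xml2::write_xml(doc, path)
  invisible(path)
}
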