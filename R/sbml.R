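# Minimal SBML Level 3 Version 2 export/import so models can move to and
# from standard systems-biology tooling. The writer emits species with
# initial concentrations, reactions with integer stoichiometries and a
# kinetic law carrying the rate-law form and its parameters as local
# parameters; the reader reconstructs a tf_model from such a document.

#' Export a model to SBML
#'
#' @param model A `tf_model`.
#' @param path Output file (.xml).
#' @return Invisibly, `path`.
#' @export
export_sbml <- function(model, path) {
  stopifnot(inherits(model, "tf_model"))
  supported <- c("irreversible_mm", "reversible_mm", "mass_action")
  forms <- vapply(model$rate_laws, function(rl) rl$form, "")
  if (length(forms) && !all(forms %in% supported))
    stop("unsupported rate-law form: ",
         paste(setdiff(forms, supported), collapse = ", "), call. = FALSE)

  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "terpflux",
                             name = paste0("glucose_to_", model$metadata$synthase))
  comp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "vial", size = "1",
                      constant = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    sp <- model$species$id[i]
    xml2::xml_add_child(los, "species", id = sp, compartment = "vial",
                        initialConcentration = format(model$init[[sp]], digits = 17),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = tolower(as.character(model$species$constant[i])),
                        constant = "false")
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rl <- model$rate_laws[[i]]
    rxn <- xml2::xml_add_child(lor, "reaction", id = model$reactions$id[i],
                               name = model$reactions$catalyst[i],
                               reversible = tolower(as.character(model$reactions$reversible[i])))
    if (length(rl$substrates)) {
      lre <- xml2::xml_add_child(rxn, "listOfReactants")
      for (s in names(rl$substrates))
        xml2::xml_add_child(lre, "speciesReference", species = s,
                            stoichiometry = as.character(rl$substrates[[s]]),
                            constant = "true")
    }
    if (length(rl$products)) {
      lpr <- xml2::xml_add_child(rxn, "listOfProducts")
      for (p in names(rl$products))
        xml2::xml_add_child(lpr, "speciesReference", species = p,
                            stoichiometry = as.character(rl$products[[p]]),
                            constant = "true")
    }
    kl <- xml2::xml_add_child(rxn, "kineticLaw")
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lp, "localParameter", id = "Vmax",
                        value = format(rl$vmax, digits = 17), units = "U_per_ml")
    if (is.finite(rl$keq))
      xml2::xml_add_child(lp, "localParameter", id = "Keq",
                          value = format(rl$keq, digits = 17))
    for (s in names(rl$km))
      xml2::xml_add_child(lp, "localParameter", id = paste0("Km_", s),
                          value = format(rl$km[[s]], digits = 17), units = "mM")
    xml2::xml_add_child(kl, "annotation", rateLawForm = rl$form)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a model from SBML written by [export_sbml()]
#'
#' @param path SBML file.
#' @param metadata Optional metadata list (synthase, product species/MW);
#'   defaults match the shipped limonene model.
#' @return A `tf_model` whose stoichiometric matrix, species, initial state
#'   and kinetic parameters reproduce the exported model.
#' @export
import_sbml <- function(path, metadata = NULL) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "id"),
    carbon = 0, phosphate = 0, adenine = 0, nicotinamide_nad = 0,
    nicotinamide_nadp = 0, coenzyme_a = 0,
    constant = xml2::xml_attr(sp_nodes, "boundaryCondition") == "true",
    stringsAsFactors = FALSE
  )
  # composition metadata is not part of core SBML: restore it from the
  # shipped composition table for known species ids
  comp <- utils::read.csv(tf_extdata("species.csv"), stringsAsFactors = FALSE)
  idx <- match(species$id, comp$id)
  for (cl in c("carbon", "phosphate", "adenine", "nicotinamide_nad",
               "nicotinamide_nadp", "coenzyme_a"))
    species[[cl]] <- ifelse(is.na(idx), 0, comp[[cl]][idx])

  init <- stats::setNames(as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")),
                          species$id)
  init[is.na(init)] <- 0

  rx_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  nr <- length(rx_nodes)
  S <- matrix(0, nrow(species), nr,
              dimnames = list(species$id,
                              xml2::xml_attr(rx_nodes, "id")))
  laws <- vector("list", nr)
  rtab <- data.frame(id = xml2::xml_attr(rx_nodes, "id"),
                     catalyst = xml2::xml_attr(rx_nodes, "name"),
                     equation = NA_character_,
                     reversible = xml2::xml_attr(rx_nodes, "reversible") == "true",
                     rate_law = NA_character_, km = NA_character_,
                     keq = NA_real_, vmax_U_per_ml = NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nr)) {
    rxn <- rx_nodes[[i]]
    get_refs <- function(xp) {
      nodes <- xml2::xml_find_all(rxn, xp, ns)
      stats::setNames(as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
                      xml2::xml_attr(nodes, "species"))
    }
    subs <- get_refs(".//s:listOfReactants/s:speciesReference")
    prods <- get_refs(".//s:listOfProducts/s:speciesReference")
    S[names(subs), i] <- S[names(subs), i] - subs
    S[names(prods), i] <- S[names(prods), i] + prods
    pars <- xml2::xml_find_all(rxn, ".//s:localParameter", ns)
    pv <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
    form <- xml2::xml_attr(xml2::xml_find_first(rxn, ".//s:annotation", ns),
                           "rateLawForm")
    km <- pv[grepl("^Km_", names(pv))]
    names(km) <- sub("^Km_", "", names(km))
    rtab$rate_law[i] <- form
    rtab$vmax_U_per_ml[i] <- pv[["Vmax"]]
    rtab$keq[i] <- if ("Keq" %in% names(pv)) pv[["Keq"]] else NA_real_
    laws[[i]] <- rate_law(form = form, vmax = pv[["Vmax"]], km = km,
                          keq = rtab$keq[i], substrates = subs,
                          products = prods)
  }
  names(laws) <- rtab$id
  if (is.null(metadata))
    metadata <- list(synthase = "limonene", product_species = "Terpene",
                     product_mw = MONOTERPENE_MW)
  structure(
    list(species = species, reactions = rtab, stoich = S, rate_laws = laws,
         init = init, metadata = metadata),
    class = "tf_model"
  )
}
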