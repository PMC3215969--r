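# Model input/output: SBML Level 3 + FBC (flux bounds, objective) and
# BiGG-style JSON, plus YAML run-condition files. Ids written to SBML carry
# the customary M_/R_ prefixes, which are stripped again on reading.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from SBML or BiGG JSON
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.xml`/`.sbml` vs `.json`),
#'   `"sbml"` or `"json"`.
#' @return An `efba_model` passing [validate_model()]; bounds and objective
#'   are preserved from the file. Species marked as boundary condition are
#'   dropped, so exchange reactions touch exactly one metabolite.
#' @export
load_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, sbml = read_sbml(path), json = read_bigg_json(path))
}

#' Write a metabolic model to SBML or BiGG JSON
#'
#' @param model an `efba_model`.
#' @param path output path.
#' @inheritParams load_model
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, sbml = write_sbml(model, path),
         json = write_bigg_json(model, path))
  invisible(path)
}

# -- SBML ------------------------------------------------------------------

# attribute lookup tolerant of namespace prefixes
ns_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1), x)
}

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML format error: ", conditionMessage(e), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) {
    stop("SBML format error: no <model> element", call. = FALSE)
  }

  comp_nodes <- xml2::xml_find_all(mdl, ".//listOfCompartments/compartment")
  compartments <- xml2::xml_attr(comp_nodes, "id")
  cn <- xml2::xml_attr(comp_nodes, "name")
  names(compartments) <- ifelse(is.na(cn), compartments, cn)

  sp <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  sid_raw <- xml2::xml_attr(sp, "id")
  mets <- tibble::tibble(
    id = strip_prefix(sid_raw, "M_"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           strip_prefix(sid_raw, "M_")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = vapply(sp, ns_attr, character(1), name = "chemicalFormula"),
    charge = suppressWarnings(
      as.numeric(vapply(sp, ns_attr, character(1), name = "charge")))
  )
  boundary_ids <- mets$id[boundary]
  mets <- mets[!boundary, ]

  params <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  pmap <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  if (!length(rx)) {
    stop("SBML format error: model has no reactions", call. = FALSE)
  }
  rid_raw <- xml2::xml_attr(rx, "id")
  rid <- strip_prefix(rid_raw, "R_")
  lookup_bound <- function(node, which, default) {
    ref <- ns_attr(node, which)
    if (is.na(ref)) return(default)
    if (ref %in% names(pmap)) return(pmap[[ref]])
    val <- suppressWarnings(as.numeric(ref))
    if (is.na(val)) {
      stop("SBML format error: flux bound parameter '", ref,
           "' is undefined", call. = FALSE)
    }
    val
  }
  rev_ <- xml2::xml_attr(rx, "reversible") %in% "true"
  lb <- ub <- numeric(length(rx))
  sto <- vector("list", length(rx))
  for (i in seq_along(rx)) {
    lb[i] <- lookup_bound(rx[[i]], "lowerFluxBound",
                          if (rev_[i]) -1000 else 0)
    ub[i] <- lookup_bound(rx[[i]], "upperFluxBound", 1000)
    rr <- xml2::xml_find_all(rx[[i]], "./listOfReactants/speciesReference")
    pp <- xml2::xml_find_all(rx[[i]], "./listOfProducts/speciesReference")
    ids <- c(strip_prefix(xml2::xml_attr(rr, "species"), "M_"),
             strip_prefix(xml2::xml_attr(pp, "species"), "M_"))
    coefs <- c(-as.numeric(xml2::xml_attr(rr, "stoichiometry")),
               as.numeric(xml2::xml_attr(pp, "stoichiometry")))
    keep <- !ids %in% boundary_ids
    if (!any(keep)) {
      stop("reaction ", rid[i], " touches only boundary species",
           call. = FALSE)
    }
    sto[[i]] <- tibble::tibble(reaction_id = rid[i],
                               metabolite_id = ids[keep],
                               coefficient = coefs[keep])
  }
  rxns <- tibble::tibble(
    id = rid,
    name = dplyr::coalesce(xml2::xml_attr(rx, "name"), rid),
    lower_bound = lb, upper_bound = ub
  )

  obj_rxn <- NULL
  fo <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfObjectives']")
  if (length(fo)) {
    active <- ns_attr(fo[[1]], "activeObjective")
    objs <- xml2::xml_find_all(fo[[1]], ".//*[local-name()='objective']")
    pick <- if (!is.na(active) && length(objs)) {
      which(vapply(objs, ns_attr, character(1), name = "id") == active)[1]
    } else 1L
    if (length(objs) && !is.na(pick)) {
      fobj <- xml2::xml_find_first(
        objs[[pick]], ".//*[local-name()='fluxObjective']")
      if (!inherits(fobj, "xml_missing")) {
        obj_rxn <- strip_prefix(ns_attr(fobj, "reaction"), "R_")
      }
    }
  }

  metabolic_model(mets, rxns, dplyr::bind_rows(sto),
                  objective_id = obj_rxn,
                  compartments = compartments,
                  id = xml2::xml_attr(mdl, "id") %||% "model")
}

num_chr <- function(x) sprintf("%.15g", x)

write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = model$id,
                             "fbc:strict" = "true")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in model$compartments) {
    xml2::xml_add_child(lc, "compartment", id = cid, constant = "true")
  }
  ls_ <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    node <- xml2::xml_add_child(
      ls_, "species", id = paste0("M_", mt$id), name = mt$name,
      compartment = mt$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (!is.na(mt$formula)) {
      xml2::xml_set_attr(node, "fbc:chemicalFormula", mt$formula)
    }
    if (!is.na(mt$charge)) {
      xml2::xml_set_attr(node, "fbc:charge", num_chr(mt$charge))
    }
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  bounds <- unique(c(model$reactions$lower_bound,
                     model$reactions$upper_bound))
  pid <- stats::setNames(paste0("fb_", seq_along(bounds)),
                         num_chr(bounds))
  for (b in bounds) {
    xml2::xml_add_child(lp, "parameter", id = pid[[num_chr(b)]],
                        value = num_chr(b), constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    node <- xml2::xml_add_child(
      lr, "reaction", id = paste0("R_", r$id), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false")
    xml2::xml_set_attr(node, "fbc:lowerFluxBound",
                       pid[[num_chr(r$lower_bound)]])
    xml2::xml_set_attr(node, "fbc:upperFluxBound",
                       pid[[num_chr(r$upper_bound)]])
    sto <- model$stoichiometry[model$stoichiometry$reaction_id == r$id, ]
    re <- sto[sto$coefficient < 0, ]
    pr <- sto[sto$coefficient > 0, ]
    if (nrow(re)) {
      lre <- xml2::xml_add_child(node, "listOfReactants")
      for (j in seq_len(nrow(re))) {
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", re$metabolite_id[j]),
                            stoichiometry = num_chr(-re$coefficient[j]),
                            constant = "true")
      }
    }
    if (nrow(pr)) {
      lpr <- xml2::xml_add_child(node, "listOfProducts")
      for (j in seq_len(nrow(pr))) {
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", pr$metabolite_id[j]),
                            stoichiometry = num_chr(pr$coefficient[j]),
                            constant = "true")
      }
    }
  }
  if (!is.null(model$objective_id)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", model$objective_id),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# -- BiGG JSON -------------------------------------------------------------

read_bigg_json <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) {
                  stop("JSON format error: ", conditionMessage(e),
                       call. = FALSE)
                })
  for (need in c("metabolites", "reactions")) {
    if (is.null(x[[need]])) {
      stop("JSON format error: missing '", need, "'", call. = FALSE)
    }
  }
  mets <- purrr::map_dfr(x$metabolites, function(m) tibble::tibble(
    id = m$id,
    name = m$name %||% m$id,
    compartment = m$compartment %||% sub("^.*_", "", m$id),
    formula = m$formula %||% NA_character_,
    charge = as.numeric(m$charge %||% NA_real_)
  ))
  rxns <- purrr::map_dfr(x$reactions, function(r) tibble::tibble(
    id = r$id,
    name = r$name %||% r$id,
    lower_bound = as.numeric(r$lower_bound %||% -1000),
    upper_bound = as.numeric(r$upper_bound %||% 1000)
  ))
  sto <- purrr::map_dfr(x$reactions, function(r) {
    if (is.null(r$metabolites) || !length(r$metabolites)) {
      stop("reaction ", r$id, " has empty stoichiometry", call. = FALSE)
    }
    tibble::tibble(reaction_id = r$id,
                   metabolite_id = names(r$metabolites),
                   coefficient = as.numeric(unlist(r$metabolites)))
  })
  objc <- vapply(x$reactions,
                 function(r) as.numeric(r$objective_coefficient %||% 0),
                 numeric(1))
  obj <- if (any(objc != 0)) rxns$id[which(objc != 0)[1]] else NULL
  comp <- if (!is.null(x$compartments) && length(x$compartments)) {
    stats::setNames(names(x$compartments),
                    unlist(x$compartments, use.names = FALSE))
  } else {
    unique(mets$compartment)
  }
  metabolic_model(mets, rxns, sto, objective_id = obj,
                  compartments = comp,
                  id = x$id %||% "model")
}

write_bigg_json <- function(model, path) {
  mets <- purrr::pmap(model$metabolites, function(id, name, compartment,
                                                  formula, charge) {
    out <- list(id = id, name = name, compartment = compartment)
    if (!is.na(formula)) out$formula <- formula
    if (!is.na(charge)) out$charge <- charge
    out
  })
  sto_split <- split(model$stoichiometry,
                     model$stoichiometry$reaction_id)
  rxns <- purrr::pmap(
    model$reactions[, c("id", "name", "lower_bound", "upper_bound")],
    function(id, name, lower_bound, upper_bound) {
      s <- sto_split[[id]]
      list(id = id, name = name,
           metabolites = as.list(stats::setNames(s$coefficient,
                                                 s$metabolite_id)),
           lower_bound = lower_bound, upper_bound = upper_bound,
           objective_coefficient =
             if (!is.null(model$objective_id) &&
                 id == model$objective_id) 1 else 0)
    })
  comp_names <- names(model$compartments) %||% model$compartments
  out <- list(
    id = model$id,
    metabolites = mets,
    reactions = rxns,
    compartments = as.list(stats::setNames(as.list(comp_names),
                                           model$compartments)),
    version = "1"
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# -- condition files -------------------------------------------------------

#' Read / write run-condition files
#'
#' Conditions serialize to YAML with keys `substrates` (map exchange id ->
#' uptake), `aerobic`, `electron_uptake_max`, `knockouts`, `pathways`.
#'
#' @param path file path.
#' @return [read_condition()] returns an [condition()];
#'   [write_condition()] returns `path` invisibly.
#' @export
read_condition <- function(path) {
  x <- yaml::read_yaml(path)
  condition(
    substrates = unlist(x$substrates %||% list()),
    aerobic = isTRUE(x$aerobic),
    electron_uptake_max = x$electron_uptake_max %||% 0,
    knockouts = unlist(x$knockouts %||% character()),
    pathways = unlist(x$pathways %||% character())
  )
}

#' @rdname read_condition
#' @param cond an [condition()].
#' @export
write_condition <- function(cond, path) {
  stopifnot(inherits(cond, "efba_condition"))
  yaml::write_yaml(
    list(substrates = as.list(cond$substrates),
         aerobic = cond$aerobic,
         electron_uptake_max = cond$electron_uptake_max,
         knockouts = as.list(cond$knockouts),
         pathways = as.list(cond$pathways)),
    path)
  invisible(path)
}
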