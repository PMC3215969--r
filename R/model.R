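#' Construct a stoichiometric metabolic model
#'
#' A metabolic model bundles a metabolite table, a reaction table with flux
#' bounds, a long-format stoichiometry table and an objective reaction. It is
#' the container every other function in the package operates on: the implied
#' stoichiometric matrix `S` has one row per metabolite and one column per
#' reaction, and flux balance analysis solves `max c'v` subject to
#' `S v = 0`, `lb <= v <= ub`.
#'
#' @param metabolites tibble with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`. `formula` may be `NA` (e.g. the electron species or
#'   a biomass pseudo-metabolite); such species are skipped by elemental
#'   balance checks.
#' @param reactions tibble with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` (fluxes in mmol/gDW-hr; the biomass reaction in 1/hr).
#' @param stoichiometry tibble with columns `reaction_id`, `metabolite_id`,
#'   `coefficient` (signed; negative = consumed).
#' @param objective_id id of the objective reaction (usually biomass).
#' @param compartments character vector of compartment ids, optionally named
#'   with display names. Derived from `metabolites` when omitted.
#' @param id optional model identifier.
#'
#' @return An object of class `efba_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective_id = NULL, compartments = NULL,
                            id = "model") {
  metabolites <- as_metabolite_tbl(metabolites)
  reactions <- as_reaction_tbl(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)
  stopifnot(all(c("reaction_id", "metabolite_id", "coefficient") %in%
                  names(stoichiometry)))
  if (is.null(compartments)) {
    compartments <- unique(metabolites$compartment)
    names(compartments) <- compartments
  }
  if (!"is_exchange" %in% names(reactions) ||
      anyNA(reactions$is_exchange)) {
    reactions$is_exchange <- flag_exchanges(reactions$id, stoichiometry)
  }
  model <- structure(
    list(
      id = id,
      metabolites = metabolites,
      reactions = reactions,
      stoichiometry = stoichiometry,
      objective_id = objective_id,
      compartments = compartments
    ),
    class = "efba_model"
  )
  validate_model(model)
  model
}

as_metabolite_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"name" %in% names(x)) x$name <- x$id
  if (!"formula" %in% names(x)) x$formula <- NA_character_
  if (!"charge" %in% names(x)) x$charge <- NA_real_
  x[, c("id", "name", "compartment", "formula", "charge")]
}

as_reaction_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"name" %in% names(x)) x$name <- x$id
  if (!"is_exchange" %in% names(x)) x$is_exchange <- NA
  x$lower_bound <- unname(as.numeric(x$lower_bound))
  x$upper_bound <- unname(as.numeric(x$upper_bound))
  x[, c("id", "name", "lower_bound", "upper_bound", "is_exchange")]
}

# An exchange touches exactly one metabolite (boundary pseudo-species are
# dropped at load time, so single-entry columns are the boundary reactions).
flag_exchanges <- function(reaction_ids, stoichiometry) {
  counts <- table(stoichiometry$reaction_id)
  unname(counts[reaction_ids] == 1 & !is.na(counts[reaction_ids]))
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, bound ordering, resolvable stoichiometry references,
#' resolvable objective, declared compartments, and that no reaction has an
#' empty stoichiometry column.
#'
#' @param model an `efba_model`.
#' @return The model, invisibly; signals a validation error otherwise.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  sto <- model$stoichiometry
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- rxns$lower_bound > rxns$upper_bound
  if (any(bad)) {
    stop("lower_bound > upper_bound for: ",
         paste(rxns$id[bad], collapse = ", "), call. = FALSE)
  }
  unknown_met <- setdiff(sto$metabolite_id, mets$id)
  if (length(unknown_met)) {
    stop("stoichiometry references unknown metabolites: ",
         paste(unknown_met, collapse = ", "), call. = FALSE)
  }
  unknown_rxn <- setdiff(sto$reaction_id, rxns$id)
  if (length(unknown_rxn)) {
    stop("stoichiometry references unknown reactions: ",
         paste(unknown_rxn, collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(rxns$id, unique(sto$reaction_id))
  if (length(empty)) {
    stop("reactions with empty stoichiometry: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  if (any(sto$coefficient == 0)) {
    stop("zero stoichiometric coefficients are not allowed", call. = FALSE)
  }
  bad_comp <- setdiff(mets$compartment, model$compartments)
  if (length(bad_comp)) {
    stop("metabolite compartments not declared: ",
         paste(bad_comp, collapse = ", "), call. = FALSE)
  }
  if (!is.null(model$objective_id) &&
      !model$objective_id %in% rxns$id) {
    stop("objective reaction not in model: ", model$objective_id,
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.efba_model <- function(x, ...) {
  cat("<efba_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  (", sum(x$reactions$is_exchange), " exchanges)\n", sep = "")
  cat("  compartments: ", paste(x$compartments, collapse = ", "), "\n",
      sep = "")
  cat("  objective: ", x$objective_id %||% "<none>", "\n", sep = "")
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#'
#' @param model an `efba_model`.
#' @return Numeric matrix, metabolites in rows, reactions in columns,
#'   dimnames from the id columns.
#' @export
stoichiometric_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  S <- matrix(0, m, n,
              dimnames = list(model$metabolites$id, model$reactions$id))
  S[cbind(match(model$stoichiometry$metabolite_id, model$metabolites$id),
          match(model$stoichiometry$reaction_id, model$reactions$id))] <-
    model$stoichiometry$coefficient
  S
}

#' Set flux bounds of one reaction
#'
#' @param model an `efba_model`.
#' @param reaction_id reaction to change.
#' @param lower,upper new bounds; `NULL` leaves a bound untouched.
#' @return A new model; the input is unmodified.
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) {
    stop("unknown reaction id: ", reaction_id, call. = FALSE)
  }
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i]) {
    stop("lower_bound > upper_bound for ", reaction_id, call. = FALSE)
  }
  model
}

#' Knock out reactions
#'
#' Sets both flux bounds of the listed reactions to zero, the in-silico
#' equivalent of a gene deletion at reaction resolution (the granularity at
#' which growth-coupled strain designs are specified). All other fields are
#' unchanged and the input model is not modified.
#'
#' @param model an `efba_model`.
#' @param reaction_ids character vector of reaction ids; an empty vector
#'   returns the model unchanged.
#' @return A new `efba_model`.
#' @export
knockout <- function(model, reaction_ids) {
  if (length(reaction_ids) == 0) return(model)
  idx <- match(reaction_ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ",
         paste(reaction_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  model$reactions$lower_bound[idx] <- 0
  model$reactions$upper_bound[idx] <- 0
  model
}

#' Add reactions (and any new metabolites) to a model
#'
#' @param model an `efba_model`.
#' @param reactions reaction tibble (`id`, `lower_bound`, `upper_bound`,
#'   optionally `name`).
#' @param stoichiometry long-format stoichiometry for the new reactions.
#' @param metabolites optional metabolite tibble for species not yet in the
#'   model.
#' @return A new `efba_model`.
#' @export
add_reactions <- function(model, reactions, stoichiometry,
                          metabolites = NULL) {
  reactions <- as_reaction_tbl(reactions)
  clash <- intersect(reactions$id, model$reactions$id)
  if (length(clash)) {
    stop("reaction ids already in model: ", paste(clash, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(metabolites) && nrow(metabolites)) {
    metabolites <- as_metabolite_tbl(metabolites)
    metabolites <- metabolites[!metabolites$id %in% model$metabolites$id, ]
    model$metabolites <- dplyr::bind_rows(model$metabolites, metabolites)
    new_comp <- setdiff(metabolites$compartment, model$compartments)
    if (length(new_comp)) {
      names(new_comp) <- new_comp
      model$compartments <- c(model$compartments, new_comp)
    }
  }
  stoichiometry <- tibble::as_tibble(stoichiometry)
  reactions$is_exchange <- flag_exchanges(reactions$id, stoichiometry)
  model$reactions <- dplyr::bind_rows(model$reactions, reactions)
  model$stoichiometry <- dplyr::bind_rows(model$stoichiometry, stoichiometry)
  validate_model(model)
  model
}

#' Exchange reactions of a model
#'
#' @param model an `efba_model`.
#' @return Tibble of exchange reactions joined with the exchanged metabolite
#'   (`metabolite_id`, `formula`, `coefficient`).
#' @export
exchanges <- function(model) {
  ex <- model$reactions[model$reactions$is_exchange, ]
  sto <- model$stoichiometry[model$stoichiometry$reaction_id %in% ex$id, ]
  out <- dplyr::left_join(ex, sto, by = c(id = "reaction_id"))
  dplyr::left_join(
    out,
    model$metabolites[, c("id", "formula", "compartment")],
    by = c(metabolite_id = "id")
  )
}

# parse "C6H12O6" / "CHO2" style formulas into a named count vector;
# pseudo-elements ("R", "A") used by the synthetic network parse the same way.
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]*)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (!length(parts) || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  el <- sub("^([A-Z][a-z]*).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]*", "", parts)
  ct <- ifelse(ct == "", 1, as.numeric(ct))
  tapply(ct, el, sum)
}

# number of carbon atoms in a metabolite formula; NA formula -> NA
carbon_count <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    v <- parse_formula(f)
    if ("C" %in% names(v)) unname(v[["C"]]) else 0
  }, numeric(1))
}

#' Check elemental balance of model reactions
#'
#' Sums element counts (from metabolite formulas) over each reaction.
#' Exchange reactions are inherently unbalanced and are skipped, as are
#' reactions touching any species without a formula (electron species,
#' biomass pseudo-species) and reactions named in
#' `exempt` (biomass equations by convention carry no balanced formula).
#'
#' @param model an `efba_model`.
#' @param exempt reaction ids to skip (default: the objective reaction).
#' @param elements which elements to check.
#' @return Tibble with one row per checked reaction: `reaction_id`,
#'   `balanced`, `imbalance` (max absolute element residual).
#' @export
check_balance <- function(model, exempt = model$objective_id,
                          elements = c("C", "H", "O", "N", "S", "P")) {
  mets <- model$metabolites
  counts <- lapply(mets$formula, function(f) {
    if (is.na(f) || !nzchar(f)) NULL else parse_formula(f)
  })
  names(counts) <- mets$id
  rxns <- model$reactions$id[!model$reactions$is_exchange]
  rxns <- setdiff(rxns, exempt)
  rows <- lapply(rxns, function(r) {
    sto <- model$stoichiometry[model$stoichiometry$reaction_id == r, ]
    cts <- counts[sto$metabolite_id]
    if (any(vapply(cts, is.null, logical(1)))) {
      return(tibble::tibble(reaction_id = r, balanced = NA,
                            imbalance = NA_real_))
    }
    tot <- stats::setNames(numeric(length(elements)), elements)
    for (i in seq_len(nrow(sto))) {
      v <- cts[[i]]
      keep <- intersect(names(v), elements)
      tot[keep] <- tot[keep] + sto$coefficient[i] * v[keep]
      extra <- setdiff(names(v), elements)
      if (length(extra)) {
        for (e in extra) {
          tot[e] <- (if (e %in% names(tot)) tot[e] else 0) +
            sto$coefficient[i] * v[[e]]
        }
      }
    }
    tibble::tibble(reaction_id = r,
                   balanced = max(abs(tot)) < 1e-9,
                   imbalance = max(abs(tot)))
  })
  dplyr::bind_rows(rows)
}
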