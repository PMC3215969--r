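#' Specify a simulation condition
#'
#' A condition describes one in-silico experiment: which substrates are fed
#' and at what maximal uptake rate, whether oxygen is available, how much
#' cathodic electron uptake is allowed, and which knockouts and heterologous
#' pathways are applied. Uptake rates are stored as positive magnitudes; the
#' underlying exchange convention is negative flux = uptake.
#'
#' The uptake rates used throughout the package follow an equal-carbon basis
#' of 60 C-mmol/gDW-hr: glucose, gluconate and sorbitol 10, xylose 12,
#' glycerol 20, maltose 5 mmol/gDW-hr (see [substrate_uptake_rates()]).
#'
#' @param substrates named numeric vector, exchange reaction id -> maximal
#'   uptake rate (mmol/gDW-hr, positive magnitude).
#' @param aerobic logical; `FALSE` closes oxygen uptake (secretion stays
#'   open).
#' @param electron_uptake_max maximal electrode electron uptake,
#'   mmol e-/gDW-hr, >= 0. The default study bound is 30.
#' @param knockouts character vector of reaction ids to disable.
#' @param pathways character vector of pathway names from
#'   [pathway_library()] to add.
#' @return An `efba_condition` object.
#' @export
condition <- function(substrates = c(EX_glc__D_e = 10), aerobic = FALSE,
                      electron_uptake_max = 0, knockouts = character(),
                      pathways = character()) {
  substrates <- unlist(substrates)
  if (length(substrates) && (is.null(names(substrates)) ||
                             any(!nzchar(names(substrates))))) {
    stop("substrates must be a named vector (exchange id -> uptake rate)",
         call. = FALSE)
  }
  if (any(substrates < 0)) {
    stop("uptake rates are positive magnitudes", call. = FALSE)
  }
  if (electron_uptake_max < 0) {
    stop("electron_uptake_max must be >= 0", call. = FALSE)
  }
  structure(
    list(substrates = substrates, aerobic = isTRUE(aerobic),
         electron_uptake_max = electron_uptake_max,
         knockouts = as.character(knockouts),
         pathways = as.character(pathways)),
    class = "efba_condition"
  )
}

#' @export
print.efba_condition <- function(x, ...) {
  cat("<efba_condition>\n")
  cat("  substrates: ",
      paste(names(x$substrates), x$substrates, sep = " = ",
            collapse = ", "), "\n", sep = "")
  cat("  aerobic: ", x$aerobic,
      "   electron_uptake_max: ", x$electron_uptake_max, "\n", sep = "")
  if (length(x$knockouts)) {
    cat("  knockouts: ", paste(x$knockouts, collapse = ", "), "\n", sep = "")
  }
  if (length(x$pathways)) {
    cat("  pathways: ", paste(x$pathways, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Equal-carbon substrate uptake rates
#'
#' The panel's maximal uptake rates on a 60 C-mmol/gDW-hr equal-carbon basis.
#' Pyruvate, used as a substrate in the ATP/biomass scenarios but absent
#' from the stated rate list, gets 20 mmol/gDW-hr on the same basis.
#'
#' @return Named numeric vector, compound -> mmol/gDW-hr.
#' @export
substrate_uptake_rates <- function() {
  c(glucose = 10, gluconate = 10, sorbitol = 10, xylose = 12,
    glycerol = 20, maltose = 5, pyruvate = 20)
}

#' Apply a condition to a model
#'
#' Returns a new model with the named substrate exchanges opened to their
#' uptake magnitude, all other carbon exchanges closed for uptake (so the
#' stated substrates are the sole organic carbon sources; CO2, bicarbonate
#' and formula-free species stay open), oxygen uptake closed when
#' `aerobic = FALSE`, pathways added, knockouts applied, and the electrode
#' electron-uptake bound set. The input model is not modified.
#'
#' @param model an `efba_model`. Must already contain electrode reactions
#'   (see [add_electrode_reactions()]) if `electron_uptake_max > 0`.
#' @param cond an [condition()] object.
#' @return A new `efba_model`.
#' @export
apply_condition <- function(model, cond) {
  stopifnot(inherits(cond, "efba_condition"))
  for (p in cond$pathways) {
    model <- add_pathway(model, pathway_library()[[p]] %||%
                           stop("unknown pathway: ", p, call. = FALSE))
  }
  ex <- exchanges(model)
  missing_sub <- setdiff(names(cond$substrates), ex$id)
  if (length(missing_sub)) {
    stop("substrate exchange(s) not in model: ",
         paste(missing_sub, collapse = ", "), call. = FALSE)
  }

  electrode_ex <- if (!is.null(model$electrode)) {
    model$electrode$exchange_id
  } else {
    "EX_e"
  }
  nC <- carbon_count(ex$formula)
  inorganic <- !is.na(ex$formula) & ex$formula %in% c("CO2", "CHO3", "CO")
  close_uptake <- ex$id[!is.na(nC) & nC > 0 & !inorganic &
                          !ex$id %in% names(cond$substrates)]
  for (rid in close_uptake) {
    i <- match(rid, model$reactions$id)
    if (model$reactions$lower_bound[i] < 0) {
      model$reactions$lower_bound[i] <- 0
    }
  }
  for (rid in names(cond$substrates)) {
    model <- set_bounds(model, rid, lower = -cond$substrates[[rid]])
  }
  if (!cond$aerobic) {
    o2 <- ex$id[!is.na(ex$formula) & ex$formula == "O2"]
    for (rid in o2) {
      i <- match(rid, model$reactions$id)
      if (model$reactions$lower_bound[i] < 0) {
        model$reactions$lower_bound[i] <- 0
      }
    }
  }
  if (electrode_ex %in% model$reactions$id) {
    model <- set_bounds(model, electrode_ex,
                        lower = -cond$electron_uptake_max)
  } else if (cond$electron_uptake_max > 0) {
    stop("condition requests electron uptake but the model has no ",
         "electrode exchange; call add_electrode_reactions() first",
         call. = FALSE)
  }
  if (length(cond$knockouts)) {
    model <- knockout(model, cond$knockouts)
  }
  model
}
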