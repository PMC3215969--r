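#' Degree-of-reduction panel
#'
#' The built-in panel of substrates and products with their NADH accounting:
#' reducing equivalents produced oxidizing a substrate to pyruvate, or
#' consumed forming a product from pyruvate, divided by the compound's
#' carbon number. The per-carbon values are stored as printed (two decimal
#' places; xylose's non-integer 1.67 NADH is taken as published) because the
#' printed table is the operational definition the SPEEQ metric is built on.
#'
#' @return Tibble with columns `compound`, `role`, `nadh`, `carbons`,
#'   `nadh_per_c`.
#' @export
speeq_panel <- function() {
  tibble::tribble(
    ~compound, ~role, ~nadh, ~carbons, ~nadh_per_c,
    "glucose", "substrate", 2, 6, 0.33,
    "xylose", "substrate", 1.67, 5, 0.33,
    "glycerol", "substrate", 2, 3, 0.67,
    "maltose", "substrate", 4, 12, 0.33,
    "sorbitol", "substrate", 3, 6, 0.50,
    "gluconate", "substrate", 1, 6, 0.17,
    "succinate", "product", 2, 4, 0.5,
    "1,3-propanediol", "product", 3, 3, 1.0,
    "1,4-butanediol", "product", 6, 4, 1.5,
    "n-butanol", "product", 4, 4, 1.0,
    "ethanol", "product", 2, 2, 1.0
  )
}

.speeq_registry <- new.env(parent = emptyenv())

#' Register a compound for degree-of-reduction lookups
#'
#' Adds (or overrides) a compound in the session's reduction-degree
#' registry, for substrates/products outside the built-in panel — e.g. the
#' species of a synthetic network.
#'
#' @param compound compound name (matching is case-insensitive).
#' @param nadh NADH produced (substrate) or consumed (product), per mole.
#' @param carbons carbon number.
#' @param nadh_per_c optional explicit per-carbon value; default
#'   `nadh / carbons`.
#' @return The per-carbon value, invisibly.
#' @export
register_compound <- function(compound, nadh, carbons,
                              nadh_per_c = nadh / carbons) {
  stopifnot(carbons > 0, nadh >= 0)
  assign(tolower(compound),
         list(nadh = nadh, carbons = carbons, nadh_per_c = nadh_per_c),
         envir = .speeq_registry)
  invisible(nadh_per_c)
}

#' Degree of reduction of a compound
#'
#' NADH equivalents per carbon, referenced to pyruvate: equivalents
#' produced during oxidation of a substrate to pyruvate, or consumed
#' producing a metabolite from pyruvate, divided by the carbon length. This
#' is the pyruvate-referenced bookkeeping of the panel, not the classical
#' elemental degree of reduction.
#'
#' @param compound name in the built-in panel (see [speeq_panel()]) or
#'   registered via [register_compound()].
#' @return NADH per carbon (dimensionless).
#' @export
degree_of_reduction <- function(compound) {
  key <- tolower(compound)
  if (exists(key, envir = .speeq_registry, inherits = FALSE)) {
    return(get(key, envir = .speeq_registry)$nadh_per_c)
  }
  panel <- speeq_panel()
  i <- match(key, tolower(panel$compound))
  if (is.na(i)) {
    stop("unknown compound '", compound, "'; known: ",
         paste(panel$compound, collapse = ", "),
         " (or register_compound())", call. = FALSE)
  }
  panel$nadh_per_c[i]
}

#' Substrate-product electron equivalence quotient (SPEEQ)
#'
#' The degree of reduction of the substrate divided by that of the product.
#' A quotient above one means the substrate is more reduced than the
#' product (little to gain from cathodic electrons); well below one marks
#' the redox-limited conversions electrical enhancement helps most.
#'
#' @param substrate,product compound names (panel or registered).
#' @return Dimensionless quotient.
#' @export
speeq <- function(substrate, product) {
  ds <- degree_of_reduction(substrate)
  dp <- degree_of_reduction(product)
  if (dp <= 0) {
    stop("product degree of reduction must be > 0 (got ", dp, " for '",
         product, "')", call. = FALSE)
  }
  ds / dp
}

#' Theoretical yield improvement across a substrate x product grid
#'
#' For every substrate-product pair, computes the maximum theoretical yield
#' (no biomass requirement, see [max_theoretical_yield()]) with the
#' electrode bound at 0 and at `electron_bound`, and relates the fractional
#' improvement to the pair's SPEEQ. Infeasible pairs are flagged, not
#' dropped. Output is sorted by SPEEQ.
#'
#' @param model an `efba_model` with electrode reactions present.
#' @param substrates tibble with columns `compound`, `exchange_id`,
#'   `uptake` (mmol/gDW-hr).
#' @param products tibble with columns `compound`, `exchange_id` and
#'   optionally `pathway` (a [pathway_library()] name, `NA` for native
#'   products).
#' @param electron_bound enhanced electron-uptake bound (mmol e-/gDW-hr).
#' @return Tibble of class `efba_speeq_grid`: one row per pair with
#'   `substrate`, `product`, `dor_substrate`, `dor_product`, `speeq`,
#'   `yield_base`, `yield_enhanced`, `improvement`, `feasible`.
#' @export
yield_improvement_grid <- function(model, substrates, products,
                                   electron_bound = 30) {
  substrates <- tibble::as_tibble(substrates)
  products <- tibble::as_tibble(products)
  if (!"pathway" %in% names(products)) products$pathway <- NA_character_
  out <- purrr::map_dfr(seq_len(nrow(products)), function(pi_) {
    prod <- products[pi_, ]
    mp <- model
    if (!is.na(prod$pathway)) {
      mp <- add_pathway(mp, pathway_library()[[prod$pathway]])
    }
    purrr::map_dfr(seq_len(nrow(substrates)), function(si_) {
      sub <- substrates[si_, ]
      cond0 <- condition(
        substrates = stats::setNames(sub$uptake, sub$exchange_id),
        electron_uptake_max = 0)
      conde <- condition(
        substrates = stats::setNames(sub$uptake, sub$exchange_id),
        electron_uptake_max = electron_bound)
      y0 <- tryCatch(
        max_theoretical_yield(mp, prod$exchange_id, cond0),
        error = function(e) NULL)
      ye <- tryCatch(
        max_theoretical_yield(mp, prod$exchange_id, conde),
        error = function(e) NULL)
      ok <- !is.null(y0) && !is.null(ye) &&
        y0$status == "optimal" && ye$status == "optimal" &&
        !is.na(y0$yield) && y0$yield > 1e-9
      tibble::tibble(
        substrate = sub$compound,
        product = prod$compound,
        dor_substrate = degree_of_reduction(sub$compound),
        dor_product = degree_of_reduction(prod$compound),
        speeq = speeq(sub$compound, prod$compound),
        yield_base = if (!is.null(y0)) y0$yield else NA_real_,
        yield_enhanced = if (!is.null(ye)) ye$yield else NA_real_,
        improvement = if (ok) ye$yield / y0$yield - 1 else NA_real_,
        feasible = ok
      )
    })
  })
  out <- dplyr::arrange(out, speeq)
  structure(out, class = c("efba_speeq_grid", class(out)),
            electron_bound = electron_bound)
}
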