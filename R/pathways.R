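# Heterologous production pathways and growth-coupled strain designs.
#
# The published reaction lists behind these pathways live in supplementary
# material that is not machine-readable here, so the stoichiometries follow
# the primary literature the routes come from (Yim et al. 1,4-butanediol;
# the clostridial CoA-dependent n-butanol route; B12-dependent glycerol
# dehydratase 1,3-propanediol; the reductive acetyl-CoA / Wood-Ljungdahl
# pathway with NADH as the reductant and one ATP at formyl-THF synthetase).
# All reduction steps use NADH; every reaction is elementally balanced
# against the formulas shipped with the specs.

pathway_met <- function(id, name, compartment, formula, charge) {
  tibble::tibble(id = id, name = name, compartment = compartment,
                 formula = formula, charge = charge)
}

# formulas/charges for species the pathways touch (BiGG conventions)
pathway_species <- function(ids) {
  all <- tibble::tribble(
    ~id, ~name, ~compartment, ~formula, ~charge,
    "nad_c", "NAD+", "c", "C21H26N7O14P2", -1,
    "nadh_c", "NADH", "c", "C21H27N7O14P2", -2,
    "h_c", "H+", "c", "H", 1,
    "h2o_c", "H2O", "c", "H2O", 0,
    "atp_c", "ATP", "c", "C10H12N5O13P3", -4,
    "adp_c", "ADP", "c", "C10H12N5O10P2", -3,
    "pi_c", "phosphate", "c", "HO4P", -2,
    "co2_c", "CO2", "c", "CO2", 0,
    "coa_c", "coenzyme A", "c", "C21H32N7O16P3S", -4,
    "accoa_c", "acetyl-CoA", "c", "C23H34N7O17P3S", -4,
    "succoa_c", "succinyl-CoA", "c", "C25H35N7O19P3S", -5,
    "ac_c", "acetate", "c", "C2H3O2", -1,
    "for_c", "formate", "c", "CHO2", -1,
    "glyc_c", "glycerol", "c", "C3H8O3", 0,
    "thf_c", "tetrahydrofolate", "c", "C19H21N7O6", -2,
    "10fthf_c", "10-formyl-THF", "c", "C20H21N7O7", -2,
    "methf_c", "5,10-methenyl-THF", "c", "C20H20N7O6", -1,
    "mlthf_c", "5,10-methylene-THF", "c", "C20H21N7O6", -2,
    "5mthf_c", "5-methyl-THF", "c", "C20H24N7O6", -1,
    "co_c", "carbon monoxide", "c", "CO", 0,
    "3hppnl_c", "3-hydroxypropanal", "c", "C3H6O2", 0,
    "13ppd_c", "1,3-propanediol", "c", "C3H8O2", 0,
    "13ppd_e", "1,3-propanediol", "e", "C3H8O2", 0,
    "sucsal_c", "succinate semialdehyde", "c", "C4H5O3", -1,
    "ghb_c", "4-hydroxybutyrate", "c", "C4H7O3", -1,
    "4hbcoa_c", "4-hydroxybutyryl-CoA", "c", "C25H38N7O18P3S", -4,
    "4hbal_c", "4-hydroxybutanal", "c", "C4H8O2", 0,
    "14bdo_c", "1,4-butanediol", "c", "C4H10O2", 0,
    "14bdo_e", "1,4-butanediol", "e", "C4H10O2", 0,
    "aacoa_c", "acetoacetyl-CoA", "c", "C25H36N7O18P3S", -4,
    "3hbcoa_c", "(S)-3-hydroxybutyryl-CoA", "c", "C25H38N7O18P3S", -4,
    "b2coa_c", "crotonyl-CoA", "c", "C25H36N7O17P3S", -4,
    "btcoa_c", "butyryl-CoA", "c", "C25H38N7O17P3S", -4,
    "btal_c", "butanal", "c", "C4H8O", 0,
    "btoh_c", "n-butanol", "c", "C4H10O", 0,
    "btoh_e", "n-butanol", "e", "C4H10O", 0
  )
  out <- all[match(ids, all$id), ]
  stopifnot(!anyNA(out$id))
  out
}

pathway_rxns <- function(stoich, bounds = NULL) {
  ids <- names(stoich)
  rx <- tibble::tibble(
    id = ids, name = ids,
    lower_bound = vapply(ids, function(r)
      if (!is.null(bounds) && r %in% names(bounds)) bounds[[r]][1] else 0,
      numeric(1)),
    upper_bound = vapply(ids, function(r)
      if (!is.null(bounds) && r %in% names(bounds)) bounds[[r]][2]
      else 1000, numeric(1))
  )
  sto <- purrr::imap_dfr(stoich, function(v, rid) {
    tibble::tibble(reaction_id = rid, metabolite_id = names(v),
                   coefficient = unname(v))
  })
  list(reactions = rx, stoichiometry = sto)
}

new_pathway <- function(name, stoich, met_ids, product_exchange_id = NA,
                        bounds = NULL, note = "") {
  pr <- pathway_rxns(stoich, bounds)
  pathway_spec(name, pr$reactions, pr$stoichiometry,
               pathway_species(met_ids), product_exchange_id, note)
}

#' Construct a pathway specification
#'
#' Low-level constructor for user-defined pathways; the built-in library
#' ([pathway_library()]) is made of these. Reaction ids must be unique and
#' absent from any model the pathway will be added to.
#'
#' @param name pathway name.
#' @param reactions reaction tibble (`id`, `lower_bound`, `upper_bound`).
#' @param stoichiometry long-format stoichiometry tibble.
#' @param metabolites metabolite tibble (with formulas where known) for all
#'   species the pathway touches; species already present in a target model
#'   are skipped at addition time.
#' @param product_exchange_id exchange id of the pathway product, `NA` for
#'   pathways without one (e.g. CO2 fixation).
#' @param note free-text description of the net conversion.
#' @return An `efba_pathway`.
#' @export
pathway_spec <- function(name, reactions, stoichiometry, metabolites,
                         product_exchange_id = NA, note = "") {
  reactions <- as_reaction_tbl(reactions)
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids in pathway", call. = FALSE)
  }
  structure(
    list(name = name, reactions = reactions,
         stoichiometry = tibble::as_tibble(stoichiometry),
         metabolites = as_metabolite_tbl(metabolites),
         product_exchange_id = product_exchange_id, note = note),
    class = "efba_pathway"
  )
}

#' @export
print.efba_pathway <- function(x, ...) {
  cat("<efba_pathway> ", x$name, " (", nrow(x$reactions), " reactions)\n",
      sep = "")
  for (r in x$reactions$id) {
    sto <- x$stoichiometry[x$stoichiometry$reaction_id == r, ]
    lhs <- sto[sto$coefficient < 0, ]
    rhs <- sto[sto$coefficient > 0, ]
    fmt <- function(s) paste(
      ifelse(abs(s$coefficient) == 1, s$metabolite_id,
             paste(abs(s$coefficient), s$metabolite_id)), collapse = " + ")
    cat("  ", r, ": ", fmt(lhs), " -> ", fmt(rhs), "\n", sep = "")
  }
  if (!is.na(x$product_exchange_id)) {
    cat("  product exchange: ", x$product_exchange_id, "\n", sep = "")
  }
  invisible(x)
}

#' Built-in heterologous pathway library
#'
#' Four pathway specifications ready to add to an *E. coli*-style model
#' (BiGG metabolite ids): `13pdo` (glycerol dehydratase + NADH-dependent
#' oxidoreductase), `14bdo` (succinyl-CoA to 1,4-butanediol via succinate
#' semialdehyde and 4-hydroxybutyrate), `nbutanol` (CoA-dependent
#' acetyl-CoA condensation route) and `wood_ljungdahl` (reductive
#' acetyl-CoA CO2 fixation; all reduction steps NADH-dependent, one ATP
#' consumed at formyl-THF synthetase — the cofactor choice the CO2-only
#' growth value is sensitive to). Production pathways include a transport
#' and a secretion-only exchange for their product.
#'
#' @return Named list of `efba_pathway` objects.
#' @export
pathway_library <- function() {
  pdo <- new_pathway(
    "13pdo",
    list(
      PDO_GLYCDH = c(glyc_c = -1, `3hppnl_c` = 1, h2o_c = 1),
      PDO_OR = c(`3hppnl_c` = -1, nadh_c = -1, h_c = -1,
                 `13ppd_c` = 1, nad_c = 1),
      PDO_T = c(`13ppd_c` = -1, `13ppd_e` = 1),
      EX_13ppd_e = c(`13ppd_e` = -1)
    ),
    c("glyc_c", "3hppnl_c", "13ppd_c", "13ppd_e", "nadh_c", "nad_c",
      "h_c", "h2o_c"),
    product_exchange_id = "EX_13ppd_e",
    note = "net: glycerol + NADH -> 1,3-propanediol"
  )
  bdo <- new_pathway(
    "14bdo",
    list(
      BDO_SSCOAR = c(succoa_c = -1, nadh_c = -1, h_c = -1,
                     sucsal_c = 1, coa_c = 1, nad_c = 1),
      BDO_4HBD = c(sucsal_c = -1, nadh_c = -1, h_c = -1,
                   ghb_c = 1, nad_c = 1),
      BDO_4HBCT = c(ghb_c = -1, accoa_c = -1, `4hbcoa_c` = 1, ac_c = 1),
      BDO_4HBALDH = c(`4hbcoa_c` = -1, nadh_c = -1, h_c = -1,
                      `4hbal_c` = 1, coa_c = 1, nad_c = 1),
      BDO_BDODH = c(`4hbal_c` = -1, nadh_c = -1, h_c = -1,
                    `14bdo_c` = 1, nad_c = 1),
      BDO_T = c(`14bdo_c` = -1, `14bdo_e` = 1),
      EX_14bdo_e = c(`14bdo_e` = -1)
    ),
    c("succoa_c", "sucsal_c", "ghb_c", "4hbcoa_c", "4hbal_c", "14bdo_c",
      "14bdo_e", "accoa_c", "ac_c", "coa_c", "nadh_c", "nad_c", "h_c"),
    product_exchange_id = "EX_14bdo_e",
    note = "4 NADH per 1,4-butanediol from succinyl-CoA"
  )
  buoh <- new_pathway(
    "nbutanol",
    list(
      BUOH_THL = c(accoa_c = -2, aacoa_c = 1, coa_c = 1),
      BUOH_HBD = c(aacoa_c = -1, nadh_c = -1, h_c = -1,
                   `3hbcoa_c` = 1, nad_c = 1),
      BUOH_CRT = c(`3hbcoa_c` = -1, b2coa_c = 1, h2o_c = 1),
      BUOH_BCD = c(b2coa_c = -1, nadh_c = -1, h_c = -1,
                   btcoa_c = 1, nad_c = 1),
      BUOH_ALDH = c(btcoa_c = -1, nadh_c = -1, h_c = -1,
                    btal_c = 1, coa_c = 1, nad_c = 1),
      BUOH_ADH = c(btal_c = -1, nadh_c = -1, h_c = -1,
                   btoh_c = 1, nad_c = 1),
      BUOH_T = c(btoh_c = -1, btoh_e = 1),
      EX_btoh_e = c(btoh_e = -1)
    ),
    c("accoa_c", "aacoa_c", "3hbcoa_c", "b2coa_c", "btcoa_c", "btal_c",
      "btoh_c", "btoh_e", "coa_c", "nadh_c", "nad_c", "h_c", "h2o_c"),
    product_exchange_id = "EX_btoh_e",
    note = "4 NADH per n-butanol from 2 acetyl-CoA"
  )
  wl <- new_pathway(
    "wood_ljungdahl",
    list(
      WL_FDH = c(co2_c = -1, nadh_c = -1, for_c = 1, nad_c = 1),
      WL_FTHFL = c(for_c = -1, thf_c = -1, atp_c = -1,
                   `10fthf_c` = 1, adp_c = 1, pi_c = 1),
      WL_MTHFC = c(`10fthf_c` = -1, h_c = -1, methf_c = 1, h2o_c = 1),
      WL_MTHFD = c(methf_c = -1, nadh_c = -1, mlthf_c = 1, nad_c = 1),
      WL_MTHFR = c(mlthf_c = -1, nadh_c = -1, h_c = -2,
                   `5mthf_c` = 1, nad_c = 1),
      WL_CODH = c(co2_c = -1, nadh_c = -1, h_c = -1,
                  co_c = 1, nad_c = 1, h2o_c = 1),
      WL_ACS = c(co_c = -1, `5mthf_c` = -1, coa_c = -1,
                 accoa_c = 1, thf_c = 1, h_c = 1)
    ),
    c("co2_c", "for_c", "thf_c", "10fthf_c", "methf_c", "mlthf_c",
      "5mthf_c", "co_c", "accoa_c", "coa_c", "nadh_c", "nad_c", "h_c",
      "h2o_c", "atp_c", "adp_c", "pi_c"),
    bounds = list(WL_MTHFC = c(-1000, 1000), WL_MTHFD = c(-1000, 1000)),
    product_exchange_id = NA,
    note = "2 CO2 + 4 NADH + ATP + CoA -> acetyl-CoA"
  )
  list(`13pdo` = pdo, `14bdo` = bdo, nbutanol = buoh, wood_ljungdahl = wl)
}

#' Add a heterologous pathway to a model
#'
#' Adds the pathway's reactions and any metabolites the model lacks; the
#' product exchange (if any) is opened for secretion only. Adding reactions
#' can only enlarge the feasible flux space, so the biomass optimum never
#' decreases.
#'
#' @param model an `efba_model`.
#' @param spec an `efba_pathway` (see [pathway_library()]) .
#' @return A new `efba_model`.
#' @export
add_pathway <- function(model, spec) {
  stopifnot(inherits(spec, "efba_pathway"))
  clash <- intersect(spec$reactions$id, model$reactions$id)
  if (length(clash)) {
    stop("pathway '", spec$name, "' reaction ids already in model: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  add_reactions(model, spec$reactions, spec$stoichiometry,
                spec$metabolites)
}

#' Growth-coupled strain design
#'
#' A named knockout set targeting one product. Knockout sets are inputs
#' (identified by external strain-design algorithms or taken from the
#' literature), never computed here.
#'
#' @param name design label.
#' @param knockouts non-empty character vector of reaction ids.
#' @param target_product product exchange reaction id.
#' @param source free-text citation note.
#' @return An `efba_strain_design`.
#' @export
strain_design <- function(name, knockouts, target_product, source = "") {
  if (!length(knockouts)) {
    stop("a strain design needs at least one knockout", call. = FALSE)
  }
  structure(list(name = name, knockouts = as.character(knockouts),
                 target_product = target_product, source = source),
            class = "efba_strain_design")
}

#' Example ethanol strain designs
#'
#' Three anaerobic ethanol-coupling knockout sets of increasing size (3, 5
#' and 10 reactions), in the style of the published OptKnock-derived
#' designs for the iAF1260 network. They are shipped as editable examples —
#' the literal published sets are not independently verifiable from here —
#' and users evaluating their own designs should supply their own sets.
#'
#' @return Named list of [strain_design()] objects keyed `eth3`, `eth5`,
#'   `eth10`.
#' @export
ethanol_example_designs <- function() {
  list(
    eth3 = strain_design(
      "ethanol 3-knockout",
      c("ACKr", "LDH_D", "FRD2"),
      "EX_etoh_e", source = "Feist-style example"),
    eth5 = strain_design(
      "ethanol 5-knockout",
      c("ACKr", "LDH_D", "FRD2", "FRD3", "PFL"),
      "EX_etoh_e", source = "Feist-style example"),
    eth10 = strain_design(
      "ethanol 10-knockout",
      c("ACKr", "LDH_D", "FRD2", "FRD3", "PFL", "PTAr", "POX", "ALCD19",
        "GLYCDx", "F6PA"),
      "EX_etoh_e", source = "Feist-style example")
  )
}

#' Growth coupling report for a strain design
#'
#' Applies the design's knockouts (on top of an optional condition),
#' maximizes biomass, then computes the minimal and maximal product flux at
#' the growth optimum. A design is growth-coupled when even the minimal
#' product flux at maximal growth is positive (tolerance 1e-6 mmol/gDW-hr).
#'
#' @param model an `efba_model` (with pathway/electrode already added as
#'   needed).
#' @param design an [strain_design()].
#' @param cond optional [condition()].
#' @param biomass_id biomass reaction; defaults to the model objective.
#' @return One-row tibble: `design`, `mu_max`, `product_min_at_mu_max`,
#'   `product_max_at_mu_max`, `coupled`.
#' @export
coupling_report <- function(model, design, cond = NULL,
                            biomass_id = model$objective_id) {
  stopifnot(inherits(design, "efba_strain_design"))
  if (!is.null(cond)) model <- apply_condition(model, cond)
  model <- knockout(model, design$knockouts)
  if (!design$target_product %in% model$reactions$id) {
    stop("target product not in model: ", design$target_product,
         call. = FALSE)
  }
  top <- solve_fba(model, biomass_id, "max")
  if (top$status != "optimal" || top$objective_value <= 1e-9) {
    return(tibble::tibble(design = design$name, mu_max = 0,
                          product_min_at_mu_max = 0,
                          product_max_at_mu_max = 0, coupled = FALSE))
  }
  mu <- top$objective_value
  mg <- set_bounds(model, biomass_id, lower = mu, upper = mu)
  lo <- solve_fba(mg, design$target_product, "min")
  hi <- solve_fba(mg, design$target_product, "max")
  pmin_ <- if (lo$status == "optimal") lo$objective_value else NA_real_
  tibble::tibble(
    design = design$name,
    mu_max = mu,
    product_min_at_mu_max = pmin_,
    product_max_at_mu_max = if (hi$status == "optimal")
      hi$objective_value else NA_real_,
    coupled = isTRUE(pmin_ > 1e-6)
  )
}
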