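#' Configuration of the synthetic fermentative network
#'
#' The synthetic ("toy") network is a minimal anaerobic fermenter whose LP
#' optima are available in closed form, so every stage of the pipeline can be
#' verified against hand mathematics: a substrate is converted by lumped
#' glycolysis into a precursor plus `n` NADH and `m` ATP, and the precursor
#' drains into a reduced product (consuming `k` NADH), an oxidized product
#' (producing 1 ATP), and a biomass drain (consuming `biomass_atp` ATP and
#' `biomass_nadh` NADH per unit precursor). NAD+/NADH and ADP/ATP/Pi are
#' conserved couples. The defaults mirror the study conditions: substrate
#' uptake 10 mmol/gDW-hr, electron-uptake bound 30 mmol e-/gDW-hr, and a
#' reduced product whose NADH demand (3) exceeds the glycolytic supply (2),
#' i.e. a fermentation whose yield is redox-limited.
#'
#' With `two_compartment = TRUE` the network gains a periplasm, a proton
#' exchange, an irreversible ATP synthase (4 periplasmic H+ + ADP + Pi ->
#' ATP + 4 cytosolic H+) and an H2-venting hydrogenase; cytosolic protons
#' have no other source, so electrode electron uptake (whose regeneration
#' reaction consumes cytosolic protons) forces ATP-synthase flux of exactly
#' (e/2)/4 — the ATP-synthase reversal mechanism at minimal scale. With
#' `include_co2_fixing_branch = TRUE` a carboxylating branch
#' (precursor + CO2 + NADH -> fixed product) mimics ppc-dependent succinate
#' formation.
#'
#' @param substrate_uptake_max maximal substrate uptake U, mmol/gDW-hr.
#' @param nadh_per_substrate `n`, NADH produced per substrate by glycolysis.
#' @param nadh_per_reduced_product `k`, NADH consumed per reduced product.
#' @param atp_per_substrate `m`, ATP produced per substrate by glycolysis.
#' @param two_compartment add periplasm, ATP synthase and hydrogenase.
#' @param include_co2_fixing_branch add the carboxylating product branch.
#' @param electron_uptake_max electrode bound `e`, mmol e-/gDW-hr.
#' @param biomass_atp,biomass_nadh ATP / NADH demand of the biomass drain
#'   per unit precursor; raising `biomass_nadh` makes growth redox-limited
#'   (electrically enhanceable), the default 1 leaves it carbon-limited.
#' @return An `efba_toy_config` list.
#' @export
toy_config <- function(substrate_uptake_max = 10, nadh_per_substrate = 2,
                       nadh_per_reduced_product = 3, atp_per_substrate = 2,
                       two_compartment = FALSE,
                       include_co2_fixing_branch = FALSE,
                       electron_uptake_max = 30,
                       biomass_atp = 2, biomass_nadh = 1) {
  cfg <- list(U = substrate_uptake_max, n = nadh_per_substrate,
              k = nadh_per_reduced_product, m = atp_per_substrate,
              two_compartment = isTRUE(two_compartment),
              co2 = isTRUE(include_co2_fixing_branch),
              e = electron_uptake_max,
              beta = biomass_atp, gamma = biomass_nadh)
  stopifnot(cfg$U > 0, cfg$n >= 0, cfg$k >= 0, cfg$m >= 0, cfg$e >= 0,
            cfg$beta >= 0, cfg$gamma >= 0)
  structure(cfg, class = "efba_toy_config")
}

#' Build the synthetic fermentative network
#'
#' Deterministic construction (no randomness) of the network described in
#' [toy_config()]. All toy species carry synthetic formulas (with `R`, `A`,
#' `P` as pseudo-elements for the cofactor moieties) so elemental-balance
#' checks apply; the biomass drain is the customary unbalanced pseudo
#' reaction and is exempt.
#'
#' @param config an [toy_config()].
#' @param with_electrode add the two electrode reactions (exchange bound
#'   from `config`); set `FALSE` to obtain the unaugmented network.
#' @param electrode_proton compartment the NADH-regeneration proton is drawn
#'   from; the toy default `"cytosol"` makes electron uptake pull protons
#'   through ATP synthase in the two-compartment variant.
#' @return An `efba_model` with objective `BIOMASS`.
#' @export
make_toy_model <- function(config = toy_config(), with_electrode = TRUE,
                           electrode_proton = c("cytosol", "periplasm")) {
  stopifnot(inherits(config, "efba_toy_config"))
  electrode_proton <- match.arg(electrode_proton)
  U <- config$U; n <- config$n; k <- config$k; m <- config$m
  beta <- config$beta; gamma <- config$gamma

  mets <- tibble::tribble(
    ~id, ~name, ~compartment, ~formula, ~charge,
    "sub_e", "substrate", "e", paste0("CH", 2 * n + 2, "O"), 0,
    "prec_c", "precursor", "c", "CH2O", 0,
    "pred_e", "reduced product", "e", paste0("CH", 2 * k + 2, "O"), 0,
    "pox_e", "oxidized product", "e", "CH2O", 0,
    "nad_c", "NAD+", "c", "R", -1,
    "nadh_c", "NADH", "c", "RH2", -2,
    "atp_c", "ATP", "c", "AP", -4,
    "adp_c", "ADP", "c", "A", -3,
    "pi_c", "phosphate", "c", "P", -2,
    "h_c", "proton (cytosol)", "c", "H", 1
  )

  sto <- list(
    EX_sub = c(sub_e = -1),
    GLYC = c(sub_e = -1, prec_c = 1,
             if (n > 0) c(nad_c = -n, nadh_c = n),
             if (m > 0) c(adp_c = -m, pi_c = -m, atp_c = m)),
    RED = c(prec_c = -1, pred_e = 1,
            if (k > 0) c(nadh_c = -k, nad_c = k)),
    EX_pred = c(pred_e = -1),
    OX = c(prec_c = -1, adp_c = -1, pi_c = -1, pox_e = 1, atp_c = 1),
    EX_pox = c(pox_e = -1),
    BIOMASS = c(prec_c = -1,
                if (beta > 0) c(atp_c = -beta, adp_c = beta, pi_c = beta),
                if (gamma > 0) c(nadh_c = -gamma, nad_c = gamma)),
    ATPM = c(atp_c = -1, adp_c = 1, pi_c = 1)
  )
  bounds <- list(EX_sub = c(-U, 1000))

  if (config$two_compartment) {
    mets <- dplyr::bind_rows(mets, tibble::tribble(
      ~id, ~name, ~compartment, ~formula, ~charge,
      "h_p", "proton (periplasm)", "p", "H", 1,
      "h2_e", "hydrogen", "e", "H2", 0
    ))
    sto$EX_h <- c(h_p = -1)
    sto$ATPS <- c(h_p = -4, adp_c = -1, pi_c = -1, atp_c = 1, h_c = 4)
    sto$HYD <- c(nadh_c = -1, nad_c = 1, h2_e = 1)
    sto$EX_h2 <- c(h2_e = -1)
    bounds$EX_h <- c(-1000, 1000)
  } else {
    sto$EX_h <- c(h_c = -1)
    bounds$EX_h <- c(-1000, 1000)
  }

  rxn_ids <- names(sto)
  rxns <- tibble::tibble(
    id = rxn_ids,
    name = rxn_ids,
    lower_bound = vapply(rxn_ids, function(r)
      if (r %in% names(bounds)) bounds[[r]][1] else 0, numeric(1)),
    upper_bound = vapply(rxn_ids, function(r)
      if (r %in% names(bounds)) bounds[[r]][2] else 1000, numeric(1))
  )
  sto_tbl <- purrr::imap_dfr(sto, function(v, rid) {
    tibble::tibble(reaction_id = rid, metabolite_id = names(v),
                   coefficient = unname(v))
  })
  model <- metabolic_model(mets, rxns, sto_tbl, objective_id = "BIOMASS",
                           compartments = unique(mets$compartment),
                           id = "toy")
  if (config$co2) {
    model <- add_pathway(model, toy_co2_branch())
  }
  if (with_electrode) {
    spec <- electrode_spec(
      electron_uptake_max = config$e,
      proton_compartment = electrode_proton,
      proton_id = if (electrode_proton == "periplasm" &&
                      config$two_compartment) "h_p" else "h_c"
    )
    model <- add_electrode_reactions(model, spec)
  }
  model
}

#' CO2-fixing branch of the synthetic network
#'
#' A one-reaction carboxylating pathway (`precursor + CO2 + 3 NADH ->
#' carboxylated product`) plus the CO2 and product exchanges. It mimics the
#' anaplerotic, NAD+-regenerating carbon fixation (ppc-style) that lets
#' electrical enhancement raise the yield of carboxylated products beyond
#' the monotone SPEEQ trend.
#'
#' @return An [pathway_spec()] addable to any toy model.
#' @export
toy_co2_branch <- function() {
  pathway_spec(
    name = "toy_co2_fix",
    reactions = tibble::tibble(
      id = c("CFIX", "EX_co2", "EX_pfix"),
      lower_bound = c(0, -1000, 0),
      upper_bound = c(1000, 1000, 1000)
    ),
    stoichiometry = tibble::tibble(
      reaction_id = c(rep("CFIX", 5), "EX_co2", "EX_pfix"),
      metabolite_id = c("prec_c", "co2_e", "nadh_c", "nad_c", "pfix_e",
                        "co2_e", "pfix_e"),
      coefficient = c(-1, -1, -3, 3, 1, -1, -1)
    ),
    metabolites = tibble::tibble(
      id = c("co2_e", "pfix_e"),
      name = c("CO2", "carboxylated product"),
      compartment = "e",
      formula = c("CO2", "C2H8O3"),
      charge = c(0, 0)
    ),
    product_exchange_id = "EX_pfix",
    note = "precursor + CO2 + 3 NADH -> carboxylated product"
  )
}

#' Closed-form optima of the synthetic network
#'
#' Analytic LP optima for the toy family, used as the independent oracle for
#' the FBA solver. Supported family: `k >= max(n, 1)` (the reduced product
#' is at least as reducing-equivalent-hungry as glycolysis is generous, the
#' redox-limited regime of interest), `biomass_atp >= 1`,
#' `0 <= biomass_nadh <= k`. Outside this family the optima remain well
#' defined but are not available as simple closed forms; use brute-force
#' vertex enumeration instead.
#'
#' All values assume the electrode present with bound
#' `config$electron_uptake_max`, electron uptake free (not forced).
#'
#' @param config an [toy_config()].
#' @return One-row tibble: `max_biomass`, `max_atp`, `max_pred`, `max_pox`
#'   (fluxes at the configured electron bound), `yield_base` and
#'   `yield_enhanced` (mol reduced product per mol substrate at bound 0 and
#'   at the configured bound), `improvement` (fractional).
#' @export
toy_reference_optima <- function(config = toy_config()) {
  stopifnot(inherits(config, "efba_toy_config"))
  U <- config$U; n <- config$n; k <- config$k; m <- config$m
  e <- config$e; beta <- config$beta; gamma <- config$gamma
  if (k < max(n, 1) || beta < 1 || gamma > k) {
    stop("config outside the closed-form family (need k >= max(n,1), ",
         "biomass_atp >= 1, biomass_nadh <= k)", call. = FALSE)
  }

  pred_at <- function(eb) min(U, (n * U + eb / 2) / k)

  if (config$two_compartment) {
    # hydrogenase vents surplus NADH; ATP synthase converts forced proton
    # influx into ATP at (e/2)/4
    max_atp <- (m + 1) * U + e / 8
    caps <- c(U, ((m + 1) * U + e / 8) / (1 + beta))
    if (gamma > 0) caps <- c(caps, (n * U + e / 2) / gamma)
    max_biomass <- min(caps)
    max_pox <- U
  } else {
    max_atp <- U * (m + 1 - n / k)
    max_pox <- U * (1 - n / k)
    # biomass: region A burns surplus NADH through the reduced product,
    # region B (NADH-limited) draws electrode electrons
    capA <- U * (m + 1 - n / k) / (1 + beta - gamma / k)
    if (gamma > 0) {
      capA_o <- if (k > gamma) U * (k - n) / (k - gamma) else Inf
      zA <- min(capA_o, capA, n * U / gamma)
      if (zA < n * U / gamma) {
        max_biomass <- zA
      } else {
        zB <- min((n * U + e / 2) / gamma, U, (m + 1) * U / (1 + beta))
        max_biomass <- max(zA, zB)
      }
    } else {
      max_biomass <- min(U * (k - n) / k, capA)
    }
  }

  yield_base <- pred_at(0) / U
  yield_enh <- pred_at(e) / U
  improvement <- if (yield_base > 0) yield_enh / yield_base - 1 else
    NA_real_
  tibble::tibble(
    max_biomass = max_biomass,
    max_atp = max_atp,
    max_pred = pred_at(e),
    max_pox = max_pox,
    yield_base = yield_base,
    yield_enhanced = yield_enh,
    improvement = improvement
  )
}
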