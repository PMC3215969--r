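# A minimal abstract host providing the precursors (succinyl-CoA,
# acetyl-CoA, NADH, ATP) that the heterologous pathways draw on, with a
# biomass drain on acetyl-CoA. Species carry no formulas: the host is
# wiring, not chemistry.

make_pathway_host <- function(atp_chem_ub = 0) {
  mets <- tibble::tibble(
    id = c("s_e", "coa_c", "succoa_c", "accoa_c", "ac_c", "nad_c",
           "nadh_c", "h_c", "h2o_c", "glyc_c", "atp_c", "adp_c", "pi_c",
           "co2_c", "thf_c"),
    compartment = c("e", rep("c", 14)),
    # formulas only where the condition logic needs to see carbon
    formula = c("C6H12O6", NA, NA, NA, "C2H3O2", NA, NA, NA, NA,
                "C3H8O3", NA, NA, NA, "CO2", NA)
  )
  rx <- tibble::tibble(
    id = c("EX_s", "MK_SUCCOA", "MK_ACCOA", "NADH_SRC", "ATP_SRC",
           "ATP_CHEM", "EX_ac", "EX_h", "EX_h2o", "EX_glyc", "EX_co2",
           "THF_SEED", "BIO"),
    lower_bound = c(-10, 0, 0, 0, 0, 0, 0, -1000, -1000, -20, -1000, -1,
                    0),
    upper_bound = c(rep(1000, 5), atp_chem_ub, rep(1000, 7))
  )
  sto <- dplyr::bind_rows(
    tibble::tibble(reaction_id = "EX_s", metabolite_id = "s_e",
                   coefficient = -1),
    tibble::tibble(reaction_id = "MK_SUCCOA",
                   metabolite_id = c("s_e", "coa_c", "succoa_c"),
                   coefficient = c(-1, -1, 1)),
    tibble::tibble(reaction_id = "MK_ACCOA",
                   metabolite_id = c("s_e", "coa_c", "accoa_c"),
                   coefficient = c(-1, -1, 1)),
    tibble::tibble(reaction_id = "NADH_SRC",
                   metabolite_id = c("s_e", "nad_c", "nadh_c"),
                   coefficient = c(-1, -1, 1)),
    tibble::tibble(reaction_id = "ATP_SRC",
                   metabolite_id = c("s_e", "adp_c", "pi_c", "atp_c"),
                   coefficient = c(-1, -1, -1, 1)),
    tibble::tibble(reaction_id = "ATP_CHEM",
                   metabolite_id = c("adp_c", "pi_c", "atp_c"),
                   coefficient = c(-1, -1, 1)),
    tibble::tibble(reaction_id = "EX_ac", metabolite_id = "ac_c",
                   coefficient = -1),
    tibble::tibble(reaction_id = "EX_h", metabolite_id = "h_c",
                   coefficient = -1),
    tibble::tibble(reaction_id = "EX_h2o", metabolite_id = "h2o_c",
                   coefficient = -1),
    tibble::tibble(reaction_id = "EX_glyc", metabolite_id = "glyc_c",
                   coefficient = -1),
    tibble::tibble(reaction_id = "EX_co2", metabolite_id = "co2_c",
                   coefficient = -1),
    tibble::tibble(reaction_id = "THF_SEED", metabolite_id = "thf_c",
                   coefficient = -1),
    tibble::tibble(reaction_id = "BIO",
                   metabolite_id = c("accoa_c", "coa_c"),
                   coefficient = c(-1, 1))
  )
  metabolic_model(mets, rx, sto, objective_id = "BIO", id = "host")
}
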