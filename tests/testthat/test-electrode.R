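# Electrode augmentation, electron/current unit conversions, electron and
# carbon conservation, and the ATP-synthase coupling motif.

test_that("electron flux / current conversions match Faraday arithmetic", {
  expect_equal(flux_to_current(30), 30e-3 * 96485 / 3600,
               tolerance = 1e-12)
  expect_equal(flux_to_current(30), 0.8040417, tolerance = 1e-7)
  expect_equal(flux_to_current(0), 0)
  expect_equal(flux_to_current(240), 6.432333, tolerance = 1e-6)
  expect_error(flux_to_current(-1), ">= 0")
  # exact inverse, to 1e-12 relative
  for (x in c(0.1, 1, 17.3, 30, 240)) {
    expect_equal(current_to_flux(flux_to_current(x)), x,
                 tolerance = 1e-12)
  }
})

test_that("current density uses the biofilm reference pair", {
  expect_equal(current_density(240), 6.432333 * 1.143 / 1.07,
               tolerance = 1e-6)
  expect_equal(current_density(0), 0)
  ident <- unit_constants(c(A_per_gDW = 1, A_per_m2 = 1))
  expect_equal(current_density(30, ident), flux_to_current(30),
               tolerance = 1e-12)
  expect_error(unit_constants(c(0, 1.143)), "positive")
})

test_that("glucose electron equivalence is 24 e- per glucose", {
  expect_equal(glucose_equivalent_electron_flux(10), 240)
  expect_equal(glucose_equivalent_electron_flux(1), 24)
  expect_equal(glucose_equivalent_electron_flux(0), 0)
  expect_error(glucose_equivalent_electron_flux(-2), ">= 0")
})

test_that("electrode augmentation adds exactly the two reactions", {
  bare <- make_toy_model(toy_config(), with_electrode = FALSE)
  aug <- add_electrode_reactions(bare, electrode_spec(
    electron_uptake_max = 30, proton_compartment = "cytosol"))
  expect_equal(nrow(aug$reactions), nrow(bare$reactions) + 2)
  expect_equal(nrow(aug$metabolites), nrow(bare$metabolites) + 1)
  # the electron species appears in the two added reactions only
  e_rxns <- unique(
    aug$stoichiometry$reaction_id[aug$stoichiometry$metabolite_id ==
                                    "e_e"])
  expect_setequal(e_rxns, c("EX_e", "NADHR"))
  i <- match("EX_e", aug$reactions$id)
  expect_equal(aug$reactions$lower_bound[i], -30)
  expect_equal(aug$reactions$upper_bound[i], 0)
  # regeneration stoichiometry is 2 e- + NAD+ + H+ -> NADH
  sto <- aug$stoichiometry[aug$stoichiometry$reaction_id == "NADHR", ]
  expect_equal(
    stats::setNames(sto$coefficient, sto$metabolite_id)[
      c("e_e", "nad_c", "h_c", "nadh_c")],
    c(e_e = -2, nad_c = -1, h_c = -1, nadh_c = 1))
  # missing prerequisites are a validation error
  broken <- make_pathway_host()
  broken$metabolites <- broken$metabolites[
    broken$metabolites$id != "nadh_c", ]
  broken$stoichiometry <- broken$stoichiometry[
    broken$stoichiometry$metabolite_id != "nadh_c", ]
  broken$reactions <- broken$reactions[
    broken$reactions$id != "NADH_SRC", ]
  expect_error(add_electrode_reactions(broken, electrode_spec(
    proton_compartment = "cytosol")), "nadh_c")
})

test_that("electron uptake equals twice the regeneration flux", {
  toy <- make_toy_model()
  for (e in c(10, 24, 30)) {
    m <- set_bounds(toy, "EX_e", lower = -e, upper = -e)
    res <- resolve_fluxes(m, "EX_pred")
    fl <- stats::setNames(res$fluxes$flux, res$fluxes$reaction)
    expect_equal(-fl[["EX_e"]], 2 * fl[["NADHR"]], tolerance = 1e-9)
  }
})

test_that("electrons alone cannot make carbon products", {
  toy <- make_toy_model(toy_config(include_co2_fixing_branch = FALSE))
  m <- set_bounds(toy, "EX_sub", lower = 0)
  expect_equal(solve_fba(m, "EX_pred")$objective_value, 0,
               tolerance = 1e-10)
  expect_equal(solve_fba(m, "EX_pox")$objective_value, 0,
               tolerance = 1e-10)
})

test_that("forced electron uptake drives ATP synthase at exactly e/8", {
  t2 <- make_toy_model(toy_config(two_compartment = TRUE),
                       electrode_proton = "cytosol")
  t2 <- set_bounds(t2, "BIOMASS", 0, 0)
  for (e in c(8, 16, 30)) {
    m <- set_bounds(t2, "EX_e", lower = -e, upper = -e)
    res <- resolve_fluxes(m, "ATPM")
    fl <- stats::setNames(res$fluxes$flux, res$fluxes$reaction)
    expect_equal(fl[["ATPS"]], e / 8, tolerance = 1e-9)
  }
  # with the periplasmic proton option the coupling disappears: protons are
  # freely exchangeable and ATP synthase stays off
  t2p <- make_toy_model(toy_config(two_compartment = TRUE),
                        electrode_proton = "periplasm")
  t2p <- set_bounds(t2p, "BIOMASS", 0, 0)
  m <- set_bounds(t2p, "EX_e", lower = -30, upper = -30)
  expect_equal(solve_fba(m, "ATPM")$objective_value, 30,
               tolerance = 1e-9)
})

test_that("optimal electron uptake covers the NADH deficit exactly", {
  # growth-coupled toy (ATP-producing drain removed): full conversion of
  # 10 substrate to the 3-NADH product needs 2*(3*10 - 2*10) = 20 e-
  cm <- knockout(make_toy_model(), "OX")
  prof <- optimal_electron_uptake(cm, "EX_pred",
                                  grid = seq(0, 30, by = 2))
  best <- prof[prof$optimal, ]
  expect_equal(best$electron_uptake, 20)
  expect_equal(best$product_flux, 10, tolerance = 1e-9)
  # points beyond the deficit-covering uptake are infeasible
  expect_true(all(is.na(prof$growth_rate[prof$electron_uptake > 20])))
  # an NADH-neutral product gains nothing from electrons
  prof_ox <- optimal_electron_uptake(make_toy_model(), "EX_pox",
                                     grid = seq(0, 20, by = 5))
  expect_equal(prof_ox$electron_uptake[prof_ox$optimal], 0)
  # all-infeasible grids are an error
  starved <- set_bounds(cm, "EX_sub", lower = 0, upper = 0)
  starved <- set_bounds(starved, "BIOMASS", lower = 1)
  expect_error(optimal_electron_uptake(starved, "EX_pred",
                                       grid = c(5, 10)),
               "infeasible")
})
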