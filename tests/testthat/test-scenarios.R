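# Named experiments: ATP / biomass enhancement, CO2 scenarios, flux-change
# summaries and the two-phase operating strategy.

cond30 <- condition(c(EX_sub = 10), electron_uptake_max = 30)

test_that("ATP scenario: no gain without the proton-coupling motif", {
  flat <- atp_max_scenario(make_toy_model(), cond30)
  expect_equal(flat$delta_abs, 0, tolerance = 1e-9)
  # electron bound 0 trivially gives no delta
  zero <- atp_max_scenario(make_toy_model(),
                           condition(c(EX_sub = 10),
                                     electron_uptake_max = 0))
  expect_equal(zero$delta_abs, 0, tolerance = 1e-12)
  expect_error(atp_max_scenario(make_pathway_host(), cond30), "ATPM")
})

test_that("ATP scenario: proton influx through ATP synthase adds e/8", {
  t2 <- make_toy_model(toy_config(two_compartment = TRUE))
  res <- atp_max_scenario(t2, cond30)
  expect_equal(res$delta_abs, 30 / 8, tolerance = 1e-9)
  expect_equal(res$base_value, 30, tolerance = 1e-9)
  # the delta is linear in the electron bound (proportional to current)
  deltas <- vapply(c(8, 16, 24), function(e) {
    atp_max_scenario(t2, condition(c(EX_sub = 10),
                                   electron_uptake_max = e))$delta_abs
  }, numeric(1))
  expect_equal(deltas, c(8, 16, 24) / 8, tolerance = 1e-9)
})

test_that("biomass scenario: gains only under redox limitation", {
  lim <- biomass_scenario(make_toy_model(toy_config(biomass_nadh = 3)),
                          cond30)
  expect_equal(lim$base_value, 20 / 3, tolerance = 1e-9)
  expect_equal(lim$enhanced_value, 10, tolerance = 1e-9)
  expect_gt(lim$delta_pct, 0)
  sur <- biomass_scenario(make_toy_model(toy_config(biomass_nadh = 1)),
                          cond30)
  expect_equal(sur$delta_abs, 0, tolerance = 1e-9)
  # relaxation: enhanced never below base
  for (g in c(0, 2)) {
    r <- biomass_scenario(make_toy_model(toy_config(biomass_nadh = g)),
                          cond30)
    expect_gte(r$enhanced_value, r$base_value - 1e-9)
  }
})

test_that("CO2 scenarios order as expected and die without fixation", {
  base <- make_toy_model(toy_config(biomass_nadh = 3))
  sc <- co2_scenarios(base, substrate_exchange = "EX_sub", uptake = 10,
                      fixation_pathway = toy_co2_branch())
  expect_identical(sc$scenario,
                   c("wild_type", "enhanced", "fixation",
                     "fixation_enhanced", "co2_only_enhanced"))
  expect_gte(sc$growth_rate[2], sc$growth_rate[1] - 1e-9)
  expect_gte(sc$growth_rate[3], sc$growth_rate[1] - 1e-9)
  expect_gte(sc$growth_rate[4], sc$growth_rate[3] - 1e-9)
  # growth yield per incoming carbon is reported where carbon enters
  expect_gt(sc$growth_yield_per_carbon[1], 0)

  # a host that can actually grow on CO2 + electrons via the reductive
  # acetyl-CoA pathway; without the pathway CO2-only growth is zero
  h <- add_electrode_reactions(
    make_pathway_host(atp_chem_ub = 5),
    electrode_spec(proton_compartment = "cytosol"))
  with_wl <- co2_scenarios(h, substrate_exchange = "EX_s", uptake = 10)
  expect_gt(with_wl$growth_rate[5], 1e-6)
  without <- co2_scenarios(h, substrate_exchange = "EX_s", uptake = 10,
                           fixation_pathway = NULL)
  expect_lt(without$growth_rate[5], 1e-9)
})

test_that("flux-change summaries compare parsimonious fits only", {
  m <- make_toy_model(toy_config(biomass_nadh = 3))
  cond <- cond30
  base <- resolve_fluxes(apply_condition(
    m, condition(c(EX_sub = 10), electron_uptake_max = 0)), "BIOMASS")
  enh <- resolve_fluxes(apply_condition(m, cond), "BIOMASS")
  groups <- pathway_groups(glycolysis = "GLYC",
                           reduced_branch = "RED",
                           oxidized_branch = "OX")
  out <- flux_change_summary(base, enh, groups)
  expect_equal(out$change_pct[out$group == "glycolysis"], 0,
               tolerance = 1e-7)
  # at the enhanced optimum all precursor goes to biomass: OX collapses
  expect_equal(out$flux_base[out$group == "oxidized_branch"], 10 / 3,
               tolerance = 1e-9)
  expect_equal(out$change_pct[out$group == "oxidized_branch"], -100,
               tolerance = 1e-6)
  # identical inputs give all-zero changes
  same <- flux_change_summary(base, base, groups)
  expect_true(all(abs(same$change_pct) < 1e-12))
  # raw (unresolved) inputs are refused
  raw <- solve_fba(apply_condition(m, cond), "BIOMASS")
  expect_error(flux_change_summary(raw, enh, groups), "resolve_fluxes")
  # groups must be disjoint and resolvable
  expect_error(pathway_groups(a = "GLYC", b = "GLYC"), "disjoint")
  expect_error(flux_change_summary(base, enh,
                                   pathway_groups(a = "NOPE")), "NOPE")
})

test_that("directionality reversal is detected", {
  # a reversible shuttle whose sign flips between conditions
  m <- make_toy_model(toy_config(two_compartment = TRUE))
  m <- set_bounds(m, "BIOMASS", 0, 0)
  base <- resolve_fluxes(set_bounds(m, "EX_e", -0, -0), "ATPM")
  enh <- resolve_fluxes(set_bounds(m, "EX_e", -30, -30), "ATPM")
  out <- flux_change_summary(base, enh, pathway_groups(atps = "ATPS"))
  expect_equal(out$flux_enhanced[1], 30 / 8, tolerance = 1e-9)
  expect_false(out$reversed[1])  # 0 -> positive is activation, not a flip
})

test_that("two-phase productivity matches its closed-form limits", {
  cm <- knockout(make_toy_model(), "OX")
  env0 <- production_envelope(
    apply_condition(cm, condition(c(EX_sub = 10),
                                  electron_uptake_max = 0)),
    "EX_pred", n_points = 11)
  env30 <- production_envelope(
    apply_condition(cm, condition(c(EX_sub = 10),
                                  electron_uptake_max = 30)),
    "EX_pred", n_points = 11)
  q1 <- env0$product_max[nrow(env0)]        # rate at mu_max (5)
  q2 <- max(env30$product_max)              # production point (10)
  mu <- attr(env0, "mu_max")

  # switch at the inoculum: pure production phase
  pure <- two_phase_productivity(env0, env30, inoculum = 0.5,
                                 substrate_pool = 100,
                                 switch_biomass = 0.5)
  expect_equal(pure$total_product, 100 * q2 / 10, tolerance = 1e-9)
  expect_equal(pure$phase1_product, 0)

  # switch never reached: single-phase growth operation
  growth_only <- two_phase_productivity(env0, env30, inoculum = 0.01,
                                        substrate_pool = 100,
                                        switch_biomass = 1e6)
  expect_false(growth_only$switched)
  expect_equal(growth_only$total_product, 100 * q1 / 10,
               tolerance = 1e-9)

  # interior switch: hand-integrated closed form
  res <- two_phase_productivity(env0, env30, inoculum = 0.01,
                                substrate_pool = 100, switch_biomass = 1)
  p1 <- q1 * (1 - 0.01) / mu
  used1 <- 10 * (1 - 0.01) / mu
  p2 <- q2 * (100 - used1) / 10
  t_expect <- log(1 / 0.01) / mu + (100 - used1) / (10 * 1)
  expect_equal(res$total_product, p1 + p2, tolerance = 1e-9)
  expect_equal(res$batch_time, t_expect, tolerance = 1e-9)

  # grid search: the best two-phase productivity beats both single phases
  grid <- c(0.01, 0.05, 0.2, 0.5, 1, 2, 5, 1e6)
  prods <- vapply(grid, function(s)
    two_phase_productivity(env0, env30, inoculum = 0.01,
                           substrate_pool = 100,
                           switch_biomass = s)$productivity, numeric(1))
  expect_gte(max(prods), prods[1] - 1e-9)           # vs pure production
  expect_gte(max(prods), prods[length(prods)] - 1e-9)  # vs pure growth
  expect_true(which.max(prods) %in% 2:(length(grid) - 1))  # interior

  expect_error(two_phase_productivity(env0, env30, inoculum = 1,
                                      switch_biomass = 0.5),
               "switch_biomass")
})
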