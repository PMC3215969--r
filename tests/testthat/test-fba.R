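# FBA engine: frozen hand-derived optima on the synthetic network,
# parsimonious resolution, theoretical yields and production envelopes.

test_that("toy optima match hand-derived values", {
  toy0 <- make_toy_model(toy_config(electron_uptake_max = 0))
  toy30 <- make_toy_model()  # default bound 30
  # redox-limited reduced product: 2 NADH supplied, 3 demanded
  expect_equal(solve_fba(toy0, "EX_pred")$objective_value, 20 / 3,
               tolerance = 1e-9)
  # electrons cover the NADH deficit; carbon becomes limiting
  expect_equal(solve_fba(toy30, "EX_pred")$objective_value, 10,
               tolerance = 1e-9)
  # maximal ATP at zero growth, NADH balance forcing the product split
  m0 <- set_bounds(toy0, "BIOMASS", 0, 0)
  expect_equal(solve_fba(m0, "ATPM")$objective_value, 70 / 3,
               tolerance = 1e-9)
  expect_equal(solve_fba(toy0, "BIOMASS")$objective_value, 5,
               tolerance = 1e-9)
})

test_that("optimal solutions satisfy steady state and bounds", {
  for (cfg in list(toy_config(), toy_config(two_compartment = TRUE),
                   toy_config(include_co2_fixing_branch = TRUE))) {
    m <- make_toy_model(cfg)
    for (oid in c("EX_pred", "BIOMASS")) {
      res <- resolve_fluxes(m, oid)
      expect_lt(steady_state_residual(m, res), 1e-6)
      v <- res$fluxes$flux
      expect_true(all(v >= m$reactions$lower_bound - 1e-7))
      expect_true(all(v <= m$reactions$upper_bound + 1e-7))
      # objective value equals the objective reaction's flux
      expect_equal(v[match(oid, res$fluxes$reaction)],
                   res$objective_value, tolerance = 1e-9)
    }
  }
})

test_that("solver failures surface as status, never a silent zero", {
  toy <- make_toy_model()
  starved <- set_bounds(set_bounds(toy, "EX_sub", lower = 0),
                        "BIOMASS", lower = 1)
  expect_equal(solve_fba(starved, "BIOMASS")$status, "infeasible")
  expect_true(is.na(solve_fba(starved, "BIOMASS")$objective_value))
  expect_error(solve_fba(toy, "NOPE"), "NOPE")

  # a free internal loop with infinite bounds is unbounded
  loop <- metabolic_model(
    tibble::tibble(id = c("a_c", "b_c"), compartment = "c"),
    tibble::tibble(id = c("F", "G"), lower_bound = 0, upper_bound = Inf),
    tibble::tibble(reaction_id = c("F", "F", "G", "G"),
                   metabolite_id = c("a_c", "b_c", "b_c", "a_c"),
                   coefficient = c(-1, 1, -1, 1)))
  expect_equal(solve_fba(loop, "F")$status, "unbounded")
})

test_that("parsimonious resolution zeroes duplicated routes", {
  toy0 <- make_toy_model(toy_config(electron_uptake_max = 0))
  # a unique optimum resolves to the same fluxes
  plain <- solve_fba(toy0, "EX_pred")
  res <- resolve_fluxes(toy0, "EX_pred")
  expect_equal(res$objective_value, plain$objective_value,
               tolerance = 1e-9)
  expect_equal(res$fluxes$flux, plain$fluxes$flux, tolerance = 1e-7)

  # duplicate the reduced-product route: the copy must carry zero
  dup <- add_reactions(
    toy0,
    tibble::tibble(id = "RED2", lower_bound = 0, upper_bound = 1000),
    tibble::tibble(reaction_id = "RED2",
                   metabolite_id = c("prec_c", "pred_e", "nadh_c",
                                     "nad_c"),
                   coefficient = c(-1, 1, -3, 3)))
  r <- resolve_fluxes(dup, "EX_pred")
  fl <- stats::setNames(r$fluxes$flux, r$fluxes$reaction)
  expect_equal(r$objective_value, 20 / 3, tolerance = 1e-9)
  expect_true(min(fl[c("RED", "RED2")]) < 1e-9)
  expect_equal(sum(fl[c("RED", "RED2")]), 20 / 3, tolerance = 1e-9)
  # total |v| not above the naive solution's
  naive <- solve_fba(dup, "EX_pred")
  expect_lte(sum(abs(r$fluxes$flux)),
             sum(abs(naive$fluxes$flux)) + 1e-7)
})

test_that("theoretical yields: 2/3 base, 1 enhanced, 50% improvement", {
  toy <- make_toy_model()
  cond0 <- condition(c(EX_sub = 10), electron_uptake_max = 0)
  cond30 <- condition(c(EX_sub = 10), electron_uptake_max = 30)
  y0 <- max_theoretical_yield(toy, "EX_pred", cond0)
  y30 <- max_theoretical_yield(toy, "EX_pred", cond30)
  expect_equal(y0$yield, 2 / 3, tolerance = 1e-9)
  expect_equal(y30$yield, 1, tolerance = 1e-9)
  expect_equal(y30$yield / y0$yield - 1, 0.5, tolerance = 1e-9)
  # biomass carries zero flux at the yield optimum
  expect_lt(abs(y30$fluxes$flux[y30$fluxes$reaction == "BIOMASS"]), 1e-9)
  expect_error(max_theoretical_yield(toy, "EX_missing"), "EX_missing")
})

test_that("production envelopes are well-formed and anchored at mu_max", {
  m <- apply_condition(knockout(make_toy_model(), "OX"),
                       condition(c(EX_sub = 10), electron_uptake_max = 0))
  env <- production_envelope(m, "EX_pred", n_points = 9)
  expect_s3_class(env, "efba_envelope")
  expect_true(all(diff(env$growth_rate) > 0))
  expect_identical(env$growth_rate[nrow(env)], attr(env, "mu_max"))
  expect_true(all(env$product_min <= env$product_max + 1e-9))
  # with the ATP drain removed, zero growth leaves the NADH surplus
  # unbalanced: nothing can be secreted
  expect_equal(env$product_max[1], 0, tolerance = 1e-9)
  # the intact network at zero growth reaches the redox-limited maximum
  env_wt <- production_envelope(
    apply_condition(make_toy_model(),
                    condition(c(EX_sub = 10), electron_uptake_max = 0)),
    "EX_pred", n_points = 5)
  expect_equal(env_wt$product_max[1], 20 / 3, tolerance = 1e-9)

  # with the electrode bound at zero the envelope equals the unaugmented
  # model's
  bare <- apply_condition(
    knockout(make_toy_model(toy_config(), with_electrode = FALSE), "OX"),
    condition(c(EX_sub = 10)))
  env_bare <- production_envelope(bare, "EX_pred", n_points = 9)
  expect_equal(env$growth_rate, env_bare$growth_rate, tolerance = 1e-9)
  expect_equal(env$product_min, env_bare$product_min, tolerance = 1e-7)
  expect_equal(env$product_max, env_bare$product_max, tolerance = 1e-7)

  starved <- set_bounds(m, "EX_sub", lower = 0, upper = 0)
  starved <- set_bounds(starved, "BIOMASS", lower = 1)
  expect_error(production_envelope(starved, "EX_pred"), "infeasible")
})

test_that("envelopes at a larger electron bound contain smaller ones", {
  base <- knockout(make_toy_model(), "OX")
  m0 <- apply_condition(base, condition(c(EX_sub = 10),
                                        electron_uptake_max = 0))
  m30 <- apply_condition(base, condition(c(EX_sub = 10),
                                         electron_uptake_max = 30))
  env0 <- production_envelope(m0, "EX_pred", n_points = 7)
  for (i in seq_len(nrow(env0))) {
    g <- env0$growth_rate[i]
    mg <- set_bounds(m30, "BIOMASS", lower = g, upper = g)
    expect_gte(solve_fba(mg, "EX_pred", "max")$objective_value,
               env0$product_max[i] - 1e-7)
    expect_lte(solve_fba(mg, "EX_pred", "min")$objective_value,
               env0$product_min[i] + 1e-7)
  }
})

test_that("tidy and glance expose fits as tibbles", {
  res <- resolve_fluxes(make_toy_model(), "EX_pred")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("reaction", "flux"))
  gl <- glance(res)
  expect_equal(gl$objective_value, 10, tolerance = 1e-9)
  expect_true(gl$resolved)
})
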