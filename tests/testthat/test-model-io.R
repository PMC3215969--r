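# Model container invariants, file round trips, conditions and knockouts.

canon_sto <- function(m) {
  dplyr::arrange(m$stoichiometry, reaction_id, metabolite_id)
}

test_that("model validation rejects broken structures", {
  toy <- make_toy_model()
  expect_error(
    metabolic_model(toy$metabolites,
                    toy$reactions,
                    dplyr::mutate(toy$stoichiometry,
                                  metabolite_id = replace(
                                    metabolite_id, 1, "ghost_c"))),
    "unknown metabolites")
  bad <- toy$reactions
  bad$lower_bound[1] <- 5
  bad$upper_bound[1] <- -5
  expect_error(metabolic_model(toy$metabolites, bad, toy$stoichiometry),
               "lower_bound")
  # an all-zero column (reaction without stoichiometry) is rejected
  extra <- dplyr::bind_rows(toy$reactions,
                            tibble::tibble(id = "EMPTY", name = "EMPTY",
                                           lower_bound = 0,
                                           upper_bound = 1,
                                           is_exchange = NA))
  expect_error(metabolic_model(toy$metabolites, extra, toy$stoichiometry),
               "empty stoichiometry")
})

test_that("SBML and JSON round trips preserve ids, stoichiometry, bounds", {
  toy <- make_toy_model(toy_config(two_compartment = TRUE,
                                   include_co2_fixing_branch = TRUE))
  for (ext in c(".xml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model(toy, path)
    back <- load_model(path)
    expect_identical(back$metabolites$id, toy$metabolites$id)
    expect_identical(back$reactions$id, toy$reactions$id)
    expect_equal(back$reactions$lower_bound, toy$reactions$lower_bound)
    expect_equal(back$reactions$upper_bound, toy$reactions$upper_bound)
    expect_equal(canon_sto(back), canon_sto(toy))
    expect_identical(back$objective_id, toy$objective_id)
    expect_identical(back$metabolites$formula, toy$metabolites$formula)
    # exchanges touch exactly one metabolite after loading
    ntouch <- table(back$stoichiometry$reaction_id)
    expect_true(all(ntouch[back$reactions$id[back$reactions$is_exchange]]
                    == 1))
    # and the loaded model solves to the same optimum
    expect_equal(solve_fba(back, "EX_pred")$objective_value,
                 solve_fba(toy, "EX_pred")$objective_value,
                 tolerance = 1e-9)
  }
})

test_that("corrupt files raise format errors without partial models", {
  xml <- withr::local_tempfile(fileext = ".xml")
  write_model(make_toy_model(), xml)
  txt <- readLines(xml, warn = FALSE)
  truncated <- withr::local_tempfile(fileext = ".xml")
  writeLines(substr(paste(txt, collapse = ""), 1, 300), truncated)
  expect_error(load_model(truncated), "format error")

  js <- withr::local_tempfile(fileext = ".json")
  writeLines("{ \"metabolites\": [", js)
  expect_error(load_model(js), "format error")
  js2 <- withr::local_tempfile(fileext = ".json")
  writeLines("{ \"reactions\": [] }", js2)
  expect_error(load_model(js2), "format error")
  expect_error(load_model(tempfile()), "not found")
})

test_that("apply_condition opens substrates, closes other carbon uptake", {
  toy <- make_toy_model()
  # start from a closed substrate and a gratuitously open product uptake
  m <- set_bounds(toy, "EX_sub", lower = 0)
  m <- set_bounds(m, "EX_pred", lower = -5)
  cond <- condition(substrates = c(EX_sub = 10), electron_uptake_max = 30)
  mc <- apply_condition(m, cond)
  rb <- function(mm, id) mm$reactions$lower_bound[mm$reactions$id == id]
  expect_equal(rb(mc, "EX_sub"), -10)
  expect_equal(rb(mc, "EX_pred"), 0)   # carbon uptake closed
  expect_equal(rb(mc, "EX_e"), -30)
  expect_equal(rb(mc, "EX_h"), -1000)  # inorganic stays open
  # purity: the input model is untouched
  expect_equal(rb(m, "EX_sub"), 0)
  expect_equal(rb(m, "EX_pred"), -5)
  # CO2 uptake stays open (inorganic carbon)
  tc <- make_toy_model(toy_config(include_co2_fixing_branch = TRUE))
  mcc <- apply_condition(tc, cond)
  expect_equal(rb(mcc, "EX_co2"), -1000)
  # unknown exchange is a validation error naming the id
  expect_error(apply_condition(toy, condition(c(EX_nope = 1))), "EX_nope")
})

test_that("anaerobic conditions close oxygen uptake only", {
  toy <- make_toy_model()
  m <- add_reactions(
    toy,
    tibble::tibble(id = "EX_o2", lower_bound = -20, upper_bound = 1000),
    tibble::tibble(reaction_id = "EX_o2", metabolite_id = "o2_e",
                   coefficient = -1),
    tibble::tibble(id = "o2_e", compartment = "e", formula = "O2",
                   charge = 0))
  mc <- apply_condition(m, condition(c(EX_sub = 10), aerobic = FALSE))
  i <- match("EX_o2", mc$reactions$id)
  expect_equal(mc$reactions$lower_bound[i], 0)
  expect_equal(mc$reactions$upper_bound[i], 1000)
  ma <- apply_condition(m, condition(c(EX_sub = 10), aerobic = TRUE))
  expect_equal(ma$reactions$lower_bound[match("EX_o2", ma$reactions$id)],
               -20)
})

test_that("a condition with nothing to grow on yields zero growth", {
  toy <- make_toy_model()
  cond <- condition(substrates = stats::setNames(numeric(0), character(0)),
                    electron_uptake_max = 0)
  mc <- apply_condition(toy, cond)
  res <- solve_fba(mc, "BIOMASS")
  expect_true(res$status != "optimal" ||
                abs(res$objective_value) < 1e-9)
})

test_that("knockout zeroes bounds, is pure, and severs routes", {
  toy <- make_toy_model()
  expect_identical(knockout(toy, character(0)), toy)
  expect_error(knockout(toy, "NOPE"), "NOPE")
  ko <- knockout(toy, "RED")
  i <- match("RED", ko$reactions$id)
  expect_equal(ko$reactions$lower_bound[i], 0)
  expect_equal(ko$reactions$upper_bound[i], 0)
  # all other fields untouched
  expect_identical(ko$reactions$id, toy$reactions$id)
  expect_equal(ko$stoichiometry, toy$stoichiometry)
  # sole route to the reduced product removed -> max flux 0
  expect_equal(solve_fba(ko, "EX_pred")$objective_value, 0,
               tolerance = 1e-10)
  # purity
  expect_equal(toy$reactions$upper_bound[i], 1000)
})

test_that("condition files round-trip through YAML", {
  cond <- condition(substrates = c(EX_sub = 12.5), aerobic = FALSE,
                    electron_uptake_max = 30,
                    knockouts = c("OX", "ATPM"),
                    pathways = "wood_ljungdahl")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_condition(cond, path)
  back <- read_condition(path)
  expect_equal(back$substrates, cond$substrates)
  expect_identical(back$aerobic, FALSE)
  expect_equal(back$electron_uptake_max, 30)
  expect_identical(back$knockouts, cond$knockouts)
  expect_identical(back$pathways, cond$pathways)
})
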