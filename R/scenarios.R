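# Named in-silico experiments: base-vs-enhanced comparisons of ATP yield,
# growth, CO2 co-utilization, flux-change summaries and the two-phase
# (grow-then-produce) operating strategy.

with_electron_bound <- function(cond, e) {
  cond$electron_uptake_max <- e
  cond
}

scenario_row <- function(scenario, objective_id, cond, base, enhanced) {
  bv <- base$objective_value
  ev <- enhanced$objective_value
  tibble::tibble(
    scenario = scenario,
    objective_id = objective_id,
    electron_uptake_max = cond$electron_uptake_max,
    base_value = bv,
    enhanced_value = ev,
    delta_abs = ev - bv,
    delta_pct = if (is.finite(bv) && abs(bv) > 1e-12)
      100 * (ev - bv) / bv else NA_real_,
    base_fit = list(base),
    enhanced_fit = list(enhanced)
  )
}

#' Maximal-ATP scenario with and without electrical enhancement
#'
#' Maximizes flux through the ATP-hydrolysis (maintenance-type) drain with
#' growth fixed to zero, once with the electrode closed and once at the
#' condition's electron-uptake bound. Maximal ATP synthesis is not a
#' physiological objective; it isolates which energy-producing pathways the
#' cathodic electrons can feed (for a proton-translocating ATP synthase,
#' one ATP per four protons pulled in, i.e. (e/2)/4 extra ATP at electron
#' uptake e).
#'
#' @param model an `efba_model` with electrode reactions.
#' @param cond an [condition()]; its `electron_uptake_max` is the enhanced
#'   bound.
#' @param atp_drain_id the ATP-hydrolysis reaction (default `"ATPM"`).
#' @param biomass_id biomass reaction to fix at zero.
#' @param zero_maintenance also drop the drain's maintenance lower bound to
#'   zero before maximizing (default keeps the model's bound).
#' @return One-row tibble: `scenario`, `base_value`, `enhanced_value`,
#'   `delta_abs`, `delta_pct` plus list-columns with the two parsimonious
#'   fits.
#' @export
atp_max_scenario <- function(model, cond, atp_drain_id = "ATPM",
                             biomass_id = model$objective_id,
                             zero_maintenance = FALSE) {
  if (!atp_drain_id %in% model$reactions$id) {
    stop("model has no ATP-hydrolysis drain '", atp_drain_id, "'",
         call. = FALSE)
  }
  prep <- function(e) {
    m <- apply_condition(model, with_electron_bound(cond, e))
    m <- set_bounds(m, biomass_id, lower = 0, upper = 0)
    if (zero_maintenance) m <- set_bounds(m, atp_drain_id, lower = 0)
    m
  }
  base <- resolve_fluxes(prep(0), atp_drain_id, "max")
  enh <- resolve_fluxes(prep(cond$electron_uptake_max), atp_drain_id,
                        "max")
  scenario_row("atp_max", atp_drain_id, cond, base, enh)
}

#' Biomass scenario with and without electrical enhancement
#'
#' Maximizes growth at electron-uptake bound zero and at the condition's
#' bound. Growth gains require the network to be redox-limited (an NADH
#' drain such as biosynthesis or a reduced-product pathway); carbon-limited
#' networks show no enhancement.
#'
#' @inheritParams atp_max_scenario
#' @return One-row tibble as in [atp_max_scenario()].
#' @export
biomass_scenario <- function(model, cond,
                             biomass_id = model$objective_id) {
  base <- resolve_fluxes(apply_condition(model, with_electron_bound(cond, 0)),
                         biomass_id, "max")
  if (base$status != "optimal") {
    stop("base condition is ", base$status, call. = FALSE)
  }
  enh <- resolve_fluxes(apply_condition(model, cond), biomass_id, "max")
  scenario_row("biomass", biomass_id, cond, base, enh)
}

#' CO2 co-utilization and CO2-only growth scenarios
#'
#' Runs the five-column comparison: wild type on substrate, substrate with
#' enhancement, substrate plus a CO2-fixing pathway, substrate plus pathway
#' with enhancement, and enhancement on CO2 as sole carbon source. Each row
#' maximizes biomass; the growth yield column reports biomass flux per unit
#' of total incoming carbon (C-mmol/gDW-hr, from the parsimonious fluxes).
#'
#' @param model an `efba_model` with electrode reactions.
#' @param substrate_exchange substrate exchange id.
#' @param uptake substrate uptake bound, mmol/gDW-hr.
#' @param electron_bound enhanced electron-uptake bound.
#' @param fixation_pathway an `efba_pathway` providing CO2 fixation
#'   (default Wood-Ljungdahl); `NULL` if the model already contains one.
#' @param biomass_id biomass reaction.
#' @return Tibble, one row per scenario, with `growth_rate`,
#'   `growth_yield_per_carbon`, `status` and a list-column `fit`.
#' @export
co2_scenarios <- function(model, substrate_exchange,
                          uptake = 10, electron_bound = 30,
                          fixation_pathway = pathway_library()$wood_ljungdahl,
                          biomass_id = model$objective_id) {
  mfix <- if (is.null(fixation_pathway)) model else
    add_pathway(model, fixation_pathway)
  sub <- stats::setNames(uptake, substrate_exchange)
  cases <- list(
    wild_type = list(m = model, cond = condition(sub,
                                                 electron_uptake_max = 0)),
    enhanced = list(m = model,
                    cond = condition(sub,
                                     electron_uptake_max = electron_bound)),
    fixation = list(m = mfix, cond = condition(sub,
                                               electron_uptake_max = 0)),
    fixation_enhanced = list(
      m = mfix,
      cond = condition(sub, electron_uptake_max = electron_bound)),
    co2_only_enhanced = list(
      m = mfix,
      cond = condition(substrates = stats::setNames(numeric(0),
                                                    character(0)),
                       electron_uptake_max = electron_bound))
  )
  purrr::imap_dfr(cases, function(cs, nm) {
    mm <- apply_condition(cs$m, cs$cond)
    fit <- tryCatch(resolve_fluxes(mm, biomass_id, "max"),
                    error = function(e) NULL)
    if (is.null(fit) || fit$status != "optimal") {
      return(tibble::tibble(scenario = nm, growth_rate = NA_real_,
                            growth_yield_per_carbon = NA_real_,
                            status = if (is.null(fit)) "error"
                                     else fit$status,
                            fit = list(fit)))
    }
    ex <- exchanges(mm)
    fl <- stats::setNames(fit$fluxes$flux, fit$fluxes$reaction)
    nC <- carbon_count(ex$formula)
    nC[is.na(nC)] <- 0
    carbon_in <- sum(pmax(0, -fl[ex$id]) * nC)
    tibble::tibble(
      scenario = nm,
      growth_rate = fit$objective_value,
      growth_yield_per_carbon = if (carbon_in > 1e-9)
        fit$objective_value / carbon_in else NA_real_,
      status = "optimal",
      fit = list(fit)
    )
  })
}

#' Named reaction groups for flux-change summaries
#'
#' @param ... named character vectors of reaction ids, or named list;
#'   optionally a vector may carry signs via a `direction` attribute-free
#'   convention: prefix a reaction id with `-` to count it with reversed
#'   sign in the group's defined direction.
#' @return Tibble with columns `group`, `reaction_id`, `direction`,
#'   validated to be disjoint.
#' @export
pathway_groups <- function(...) {
  lst <- list(...)
  if (length(lst) == 1 && is.list(lst[[1]]) && is.null(names(lst))) {
    lst <- lst[[1]]
  }
  if (is.null(names(lst)) || any(!nzchar(names(lst)))) {
    stop("groups must be named", call. = FALSE)
  }
  out <- purrr::imap_dfr(lst, function(ids, nm) {
    neg <- startsWith(ids, "-")
    tibble::tibble(group = nm, reaction_id = sub("^-", "", ids),
                   direction = ifelse(neg, -1, 1))
  })
  if (anyDuplicated(out$reaction_id)) {
    stop("groups must be disjoint; duplicated: ",
         paste(unique(out$reaction_id[duplicated(out$reaction_id)]),
               collapse = ", "), call. = FALSE)
  }
  out
}

#' Flux changes through reaction groups under enhancement
#'
#' Compares two degeneracy-resolved flux distributions group by group:
#' fluxes are summed in each group's defined direction and the enhanced sum
#' is reported as a percent change of the base sum (positive = increased
#' magnitude in the defined direction). Inputs must come from
#' [resolve_fluxes()] — raw alternate optima would make the comparison an
#' artifact of the solver path.
#'
#' @param base,enhanced `efba_fba` objects with `resolved = TRUE`.
#' @param groups a [pathway_groups()] tibble.
#' @return Tibble: `group`, `flux_base`, `flux_enhanced`, `change_pct`,
#'   `reversed` (direction flip); attribute `detail` holds the
#'   per-reaction table.
#' @export
flux_change_summary <- function(base, enhanced, groups) {
  stopifnot(inherits(base, "efba_fba"), inherits(enhanced, "efba_fba"))
  if (!isTRUE(base$resolved) || !isTRUE(enhanced$resolved)) {
    stop("flux_change_summary requires parsimonious (resolved) inputs; ",
         "use resolve_fluxes()", call. = FALSE)
  }
  fb <- stats::setNames(base$fluxes$flux, base$fluxes$reaction)
  fe <- stats::setNames(enhanced$fluxes$flux, enhanced$fluxes$reaction)
  missing <- setdiff(groups$reaction_id, names(fb))
  if (length(missing)) {
    stop("group reaction(s) not in flux distribution: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  detail <- dplyr::mutate(
    groups,
    flux_base = .data$direction * fb[.data$reaction_id],
    flux_enhanced = .data$direction * fe[.data$reaction_id]
  )
  out <- dplyr::summarise(
    dplyr::group_by(detail, .data$group),
    flux_base = sum(.data$flux_base),
    flux_enhanced = sum(.data$flux_enhanced),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    change_pct = dplyr::if_else(
      abs(.data$flux_base) > 1e-9,
      100 * (.data$flux_enhanced - .data$flux_base) / abs(.data$flux_base),
      dplyr::if_else(abs(.data$flux_enhanced) > 1e-9, Inf, 0)),
    reversed = .data$flux_base * .data$flux_enhanced < -1e-12
  )
  attr(out, "detail") <- detail
  out
}

#' Two-phase (grow, then produce) batch productivity
#'
#' Closed-form operating-point calculator for the dynamic strategy: grow
#' exponentially with no (or low) current at the growth envelope's maximum
#' growth rate until a switch biomass density is reached, then hold biomass
#' and produce at the production envelope's maximum-product operating point
#' until the substrate pool is exhausted. No ODEs: exponential-phase
#' consumption integrates in closed form. Product inhibition and
#' maintenance decay are ignored.
#'
#' @param envelope_growth [production_envelope()] of the growth-phase model
#'   (e.g. electrode closed); its `mu_max` and the product rate at `mu_max`
#'   define phase 1.
#' @param envelope_prod envelope of the production-phase model (e.g.
#'   electrode at full current); its maximum `product_max` defines the
#'   phase-2 specific production rate.
#' @param inoculum starting biomass, gDW/L.
#' @param substrate_pool substrate available, mmol/L.
#' @param switch_biomass biomass density triggering the switch, gDW/L
#'   (>= inoculum).
#' @param substrate_uptake specific substrate uptake rate at both operating
#'   points, mmol/gDW-hr.
#' @return One-row tibble: `total_product` (mmol/L), `batch_time` (hr),
#'   `productivity` (mmol/L-hr), `phase1_product`, `phase2_product`,
#'   `switched` (logical: was phase 2 reached).
#' @export
two_phase_productivity <- function(envelope_growth, envelope_prod,
                                   inoculum = 0.01, substrate_pool = 100,
                                   switch_biomass = 1,
                                   substrate_uptake = 10) {
  stopifnot(inherits(envelope_growth, "efba_envelope"),
            inherits(envelope_prod, "efba_envelope"))
  if (switch_biomass < inoculum) {
    stop("switch_biomass must be >= inoculum", call. = FALSE)
  }
  if (min(inoculum, substrate_pool, substrate_uptake) <= 0) {
    stop("parameters must be positive", call. = FALSE)
  }
  mu <- attr(envelope_growth, "mu_max")
  if (mu <= 1e-9) stop("growth envelope has mu_max ~ 0", call. = FALSE)
  q1 <- envelope_growth$product_max[nrow(envelope_growth)]  # at mu_max
  q2 <- max(envelope_prod$product_max, na.rm = TRUE)
  s <- substrate_uptake

  # phase 1: X(t) = X0 exp(mu t); substrate use s/mu * (X1 - X0)
  dX_switch <- switch_biomass - inoculum
  sub_phase1 <- s * dX_switch / mu
  if (sub_phase1 >= substrate_pool) {
    x_end <- inoculum + mu * substrate_pool / s
    t1 <- log(x_end / inoculum) / mu
    p1 <- q1 * substrate_pool / s
    return(tibble::tibble(total_product = p1, batch_time = t1,
                          productivity = p1 / t1,
                          phase1_product = p1, phase2_product = 0,
                          switched = FALSE))
  }
  t1 <- if (dX_switch > 0) log(switch_biomass / inoculum) / mu else 0
  p1 <- q1 * dX_switch / mu
  remaining <- substrate_pool - sub_phase1
  t2 <- remaining / (s * switch_biomass)
  p2 <- q2 * remaining / s
  total <- p1 + p2
  tt <- t1 + t2
  tibble::tibble(total_product = total, batch_time = tt,
                 productivity = total / tt,
                 phase1_product = p1, phase2_product = p2,
                 switched = TRUE)
}
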