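#' Solve a flux balance analysis problem
#'
#' Optimizes the flux of one reaction subject to steady state (`S v = 0`) and
#' the model's flux bounds, the core linear program of constraint-based
#' metabolic modeling. The optimum of the LP is unique even when the
#' optimizing flux vector is not; use [resolve_fluxes()] when the full flux
#' distribution is to be reported.
#'
#' @param model an `efba_model`.
#' @param objective_id reaction to optimize; defaults to the model objective.
#' @param direction `"max"` or `"min"`.
#' @return An `efba_fba` object: `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective_value`, and `fluxes`, a tibble with columns
#'   `reaction` and `flux`.
#' @export
solve_fba <- function(model, objective_id = model$objective_id,
                      direction = c("max", "min")) {
  direction <- match.arg(direction)
  j <- match(objective_id, model$reactions$id)
  if (is.na(j)) {
    stop("objective reaction not in model: ", objective_id, call. = FALSE)
  }
  S <- stoichiometric_matrix(model)
  obj <- numeric(ncol(S))
  obj[j] <- 1
  sol <- lp_solve(obj, S, lb = model$reactions$lower_bound,
                  ub = model$reactions$upper_bound, direction = direction)
  if (!sol$status %in% c("optimal", "infeasible", "unbounded")) {
    stop("LP solver failed with status '", sol$status, "' while optimizing ",
         objective_id, call. = FALSE)
  }
  new_fba_result(sol, model, objective_id, direction, resolved = FALSE)
}

new_fba_result <- function(sol, model, objective_id, direction, resolved) {
  structure(
    list(
      status = sol$status,
      objective_value = if (sol$status == "optimal") sol$objective
                        else NA_real_,
      fluxes = tibble::tibble(reaction = model$reactions$id, flux = sol$x),
      objective_id = objective_id,
      direction = direction,
      resolved = resolved
    ),
    class = "efba_fba"
  )
}

#' @export
print.efba_fba <- function(x, ...) {
  cat("<efba_fba> ", x$direction, " ", x$objective_id, ": ", sep = "")
  if (x$status == "optimal") {
    cat(format(x$objective_value, digits = 6),
        if (x$resolved) " (parsimonious)\n" else "\n", sep = "")
  } else {
    cat(x$status, "\n")
  }
  invisible(x)
}

#' Degeneracy-resolved (parsimonious) flux distribution
#'
#' Among the alternate optima of [solve_fba()] — the objective pinned at its
#' optimal value — returns the flux vector with minimal total absolute flux.
#' Reported flux tables should always come from this function: raw optimal
#' vertices are solver-dependent, the parsimonious one is reproducible.
#'
#' @inheritParams solve_fba
#' @return An `efba_fba` with `resolved = TRUE`; `objective_value` is
#'   identical to [solve_fba()]'s.
#' @export
resolve_fluxes <- function(model, objective_id = model$objective_id,
                           direction = c("max", "min")) {
  direction <- match.arg(direction)
  base <- solve_fba(model, objective_id, direction)
  if (base$status != "optimal") return(base)
  zstar <- base$objective_value

  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  # split v = vp - vm, vp, vm >= 0; minimize sum(vp + vm)
  lp_ <- pmax(0, lb); up_ <- pmax(0, ub)
  lm_ <- pmax(0, -ub); um_ <- pmax(0, -lb)
  j <- match(objective_id, model$reactions$id)
  crow <- numeric(2 * n)
  crow[j] <- 1
  crow[n + j] <- -1
  A2 <- rbind(cbind(S, -S), crow)
  b2 <- c(numeric(nrow(S)), zstar)
  sol <- lp_solve(rep(1, 2 * n), A2, b = b2, lb = c(lp_, lm_),
                  ub = c(up_, um_), direction = "min")
  if (sol$status != "optimal") {
    stop("parsimonious resolution failed (status '", sol$status,
         "'); base optimum was ", zstar, call. = FALSE)
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  new_fba_result(list(status = "optimal", objective = v[j], x = v),
                 model, objective_id, direction, resolved = TRUE)
}

#' Maximum theoretical product yield
#'
#' Maximizes a product exchange flux with growth left unconstrained — the
#' theoretical maximum occurs with no biomass synthesis, so the biomass
#' reaction is free to (and at the optimum does) carry zero flux. Any
#' electrode electron uptake present in the model is likewise free between 0
#' and its bound; the optimizer picks whatever uptake maximizes the product.
#'
#' @param model an `efba_model` (conditioned, or pass `condition`).
#' @param product_exchange_id exchange reaction of the product.
#' @param condition optional [condition()] applied before solving.
#' @param basis `"substrate"` (default) computes mol product per mol
#'   substrate taken up; `"carbon"` divides carbon secreted as product by all
#'   incoming carbon including fixed CO2.
#' @return An `efba_fba` (parsimonious) with extra fields `yield`,
#'   `substrate_uptake` (mmol/gDW-hr, positive) and `product_id`.
#' @export
max_theoretical_yield <- function(model, product_exchange_id,
                                  condition = NULL,
                                  basis = c("substrate", "carbon")) {
  basis <- match.arg(basis)
  if (!is.null(condition)) model <- apply_condition(model, condition)
  if (!product_exchange_id %in% model$reactions$id) {
    stop("product exchange not in model: ", product_exchange_id,
         call. = FALSE)
  }
  res <- resolve_fluxes(model, product_exchange_id, "max")
  if (res$status != "optimal") {
    res$yield <- NA_real_
    res$substrate_uptake <- NA_real_
    res$product_id <- product_exchange_id
    return(res)
  }
  ex <- exchanges(model)
  fl <- stats::setNames(res$fluxes$flux, res$fluxes$reaction)
  upt <- -pmin(0, fl[ex$id])            # uptake magnitudes
  nC <- carbon_count(ex$formula)
  nC[is.na(nC)] <- 0
  is_sub <- upt > 1e-9 & nC > 0 & ex$id != product_exchange_id
  if (basis == "substrate") {
    co2_like <- nC == 1 & !is.na(ex$formula) &
      ex$formula %in% c("CO2", "CHO3", "CO")
    denom <- sum(upt[is_sub & !co2_like])
    y <- if (denom > 1e-9) res$objective_value / denom else NA_real_
  } else {
    prod_c <- nC[match(product_exchange_id, ex$id)]
    denom <- sum(upt[is_sub] * nC[is_sub])
    y <- if (denom > 1e-9) res$objective_value * prod_c / denom
         else NA_real_
  }
  res$yield <- unname(y)
  res$substrate_uptake <- unname(sum(upt[is_sub]))
  res$product_id <- product_exchange_id
  res
}

#' Production envelope of a product against growth
#'
#' Computes the attainable minimum and maximum product flux at each of
#' `n_points` growth rates evenly spaced on `[0, mu_max]`, with the maximal
#' growth rate included exactly so that coupling at full growth is never
#' interpolated. Electron uptake (if an electrode is present) is free within
#' its bound at every point, so envelopes at larger electron-uptake bounds
#' contain envelopes at smaller ones pointwise.
#'
#' @param model an `efba_model`.
#' @param product_exchange_id exchange reaction of the product.
#' @param biomass_id biomass reaction; defaults to the model objective.
#' @param n_points number of growth values (>= 2).
#' @param condition optional [condition()] applied first.
#' @return A tibble of class `efba_envelope` with columns `growth_rate`,
#'   `product_min`, `product_max`; attributes `product_id`, `biomass_id`,
#'   `electron_uptake_max`, `mu_max`.
#' @export
production_envelope <- function(model, product_exchange_id,
                                biomass_id = model$objective_id,
                                n_points = 50, condition = NULL) {
  stopifnot(n_points >= 2)
  if (!is.null(condition)) model <- apply_condition(model, condition)
  for (rid in c(product_exchange_id, biomass_id)) {
    if (!rid %in% model$reactions$id) {
      stop("reaction not in model: ", rid, call. = FALSE)
    }
  }
  top <- solve_fba(model, biomass_id, "max")
  if (top$status != "optimal") {
    stop("base model is ", top$status, "; cannot sample an envelope",
         call. = FALSE)
  }
  mu_max <- max(0, top$objective_value)
  grid <- unique(c(seq(0, mu_max, length.out = n_points)))
  grid[length(grid)] <- mu_max
  rows <- purrr::map(grid, function(g) {
    mg <- set_bounds(model, biomass_id, lower = g, upper = g)
    lo <- solve_fba(mg, product_exchange_id, "min")
    hi <- solve_fba(mg, product_exchange_id, "max")
    tibble::tibble(
      growth_rate = g,
      product_min = if (lo$status == "optimal") lo$objective_value
                    else NA_real_,
      product_max = if (hi$status == "optimal") hi$objective_value
                    else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  e_max <- electron_bound(model)
  structure(out,
            class = c("efba_envelope", class(out)),
            product_id = product_exchange_id,
            biomass_id = biomass_id,
            electron_uptake_max = e_max,
            mu_max = mu_max)
}

# current electron-uptake bound of a model, 0 when no electrode exchange
electron_bound <- function(model, exchange_id = "EX_e") {
  i <- match(exchange_id, model$reactions$id)
  if (is.na(i)) 0 else -model$reactions$lower_bound[i]
}

#' Steady-state residual of an FBA solution
#'
#' @param model the model the result was solved on.
#' @param result an `efba_fba`.
#' @return `max |S v|`, which should be below 1e-6 for optimal results.
#' @export
steady_state_residual <- function(model, result) {
  stopifnot(inherits(result, "efba_fba"), result$status == "optimal")
  S <- stoichiometric_matrix(model)
  v <- result$fluxes$flux[match(colnames(S), result$fluxes$reaction)]
  max(abs(S %*% v))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy efba_fba
#' @rdname solve_fba
#' @param x an `efba_fba` object.
#' @param ... unused.
tidy.efba_fba <- function(x, ...) {
  x$fluxes
}

#' @export
#' @method glance efba_fba
#' @rdname solve_fba
glance.efba_fba <- function(x, ...) {
  tibble::tibble(
    objective_id = x$objective_id,
    direction = x$direction,
    status = x$status,
    objective_value = x$objective_value,
    resolved = x$resolved,
    n_active = sum(abs(x$fluxes$flux) > 1e-9, na.rm = TRUE),
    total_abs_flux = sum(abs(x$fluxes$flux), na.rm = TRUE)
  )
}
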