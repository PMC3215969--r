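# Brute-force LP oracle: enumerates every basic solution (vertex) of
# { x : A x = b, lb <= x <= ub } and reports the best objective value.
# Completely independent of the package's simplex; only usable for tiny
# problems (cost ~ choose(n, rank) * 2^(n - rank)).

enumerate_lp_optimum <- function(obj, A, b = NULL, lb, ub,
                                 direction = "max") {
  A <- as.matrix(A)
  n <- ncol(A)
  if (is.null(b)) b <- numeric(nrow(A))
  # keep an independent row subset
  qt <- qr(t(A))
  rk <- qt$rank
  if (rk > 0) {
    rows <- qt$pivot[seq_len(rk)]
    # b must be consistent on dropped rows for b = 0 this is automatic;
    # only b = 0 is used here
    stopifnot(all(b == 0) || rk == nrow(A))
    A <- A[rows, , drop = FALSE]
    b <- b[rows]
  } else {
    A <- matrix(0, 0, n)
    b <- numeric(0)
  }
  m <- nrow(A)
  best <- if (direction == "max") -Inf else Inf
  better <- if (direction == "max") function(a, b) a > b else
    function(a, b) a < b
  feasible <- FALSE

  if (m == 0) {
    x <- ifelse((direction == "max") == (obj > 0), ub, lb)
    x[obj == 0] <- lb[obj == 0]
    return(list(feasible = all(lb <= ub), objective = sum(obj * x)))
  }

  combos <- utils::combn(n, m)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n - m)))
  for (ci in seq_len(ncol(combos))) {
    B <- combos[, ci]
    NB <- setdiff(seq_len(n), B)
    qa <- qr(A[, B, drop = FALSE])
    if (qa$rank < m) next
    for (gi in seq_len(nrow(grid))) {
      xN <- ifelse(grid[gi, ], ub[NB], lb[NB])
      rhs <- b - A[, NB, drop = FALSE] %*% xN
      xB <- qr.coef(qa, rhs)
      if (anyNA(xB)) next
      if (all(xB >= lb[B] - 1e-9 & xB <= ub[B] + 1e-9)) {
        feasible <- TRUE
        x <- numeric(n)
        x[B] <- xB
        x[NB] <- xN
        val <- sum(obj * x)
        if (better(val, best)) best <- val
      }
    }
  }
  list(feasible = feasible,
       objective = if (feasible) best else NA_real_)
}

# vertex-enumeration optimum of one reaction flux on a (tiny) model
enumerate_fba_optimum <- function(model, objective_id, direction = "max") {
  S <- stoichiometric_matrix(model)
  obj <- numeric(ncol(S))
  obj[match(objective_id, model$reactions$id)] <- 1
  enumerate_lp_optimum(obj, S, lb = model$reactions$lower_bound,
                       ub = model$reactions$upper_bound,
                       direction = direction)
}

# toy model with the electrode attached, biomass pinned to zero on request
toy_with <- function(..., with_electrode = TRUE,
                     electrode_proton = "cytosol", no_growth = FALSE) {
  m <- make_toy_model(toy_config(...), with_electrode = with_electrode,
                      electrode_proton = electrode_proton)
  if (no_growth) m <- set_bounds(m, "BIOMASS", lower = 0, upper = 0)
  m
}

expect_close <- function(actual, expected, tol = 1e-9) {
  testthat::expect_true(
    abs(actual - expected) <= tol,
    label = sprintf("|%.12g - %.12g| <= %g", actual, expected, tol))
}
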