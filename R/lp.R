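# Bounded-variable primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# with a two-phase method: phase 1 drives artificial variables out of the
# basis, phase 2 optimizes the real objective. The basis system is refactored
# from scratch every iteration (dense `solve`), which is numerically
# self-correcting and entirely adequate for the problem sizes this package
# optimizes routinely (tens to a few thousand columns). Dantzig pricing with
# a switch to Bland's rule guards against cycling on the degenerate vertices
# that metabolic networks produce in abundance.
#
# Infinite variable bounds are clamped to +/- .efba_big; if the optimum
# leans on a clamped bound the problem is re-solved with a wider clamp to
# distinguish a genuinely unbounded LP from a merely large optimum.

.efba_big <- 1e6

lp_solve <- function(obj, A, b = NULL, lb, ub, direction = c("max", "min"),
                     tol = 1e-9, feas_tol = 1e-7, max_iter = NULL,
                     .big = .efba_big) {
  direction <- match.arg(direction)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == m)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }

  clamped_lo <- is.infinite(lb)
  clamped_hi <- is.infinite(ub)
  lb2 <- ifelse(clamped_lo, -.big, lb)
  ub2 <- ifelse(clamped_hi, .big, ub)

  sgn <- if (direction == "max") 1 else -1
  res <- simplex_core(sgn * obj, A, b, lb2, ub2, tol = tol,
                      feas_tol = feas_tol, max_iter = max_iter)
  if (res$status == "optimal" && (any(clamped_lo) || any(clamped_hi))) {
    at_clamp <- (clamped_hi & res$x > .big - 1) |
      (clamped_lo & res$x < -.big + 1)
    if (any(at_clamp)) {
      res2 <- simplex_core(sgn * obj, A, b,
                           ifelse(clamped_lo, -100 * .big, lb),
                           ifelse(clamped_hi, 100 * .big, ub),
                           tol = tol, feas_tol = feas_tol,
                           max_iter = max_iter)
      if (res2$status != "optimal" ||
          abs(res2$objective - res$objective) >
            1e-6 * max(1, abs(res$objective))) {
        return(list(status = "unbounded", objective = NA_real_,
                    x = rep(NA_real_, n)))
      }
    }
  }
  if (res$status == "optimal") {
    res$objective <- sum(obj * res$x)
  } else {
    res$objective <- NA_real_
    res$x <- rep(NA_real_, n)
  }
  res
}

# maximization core with all-finite bounds
simplex_core <- function(cc, A, b, lb, ub, tol = 1e-9, feas_tol = 1e-7,
                         max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 100L * (n + m) + 500L

  # start all structural variables nonbasic at the bound nearer zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper <- abs(lb) > abs(ub)

  if (m == 0L) {
    # box problem: each variable at its favourable bound
    x <- ifelse(cc > 0, ub, ifelse(cc < 0, lb, x))
    return(list(status = "optimal", objective = sum(cc * x), x = x))
  }

  r <- b - as.vector(A %*% x)
  art_sign <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(art_sign, m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(Inf, m))
  xall <- c(x, abs(r))
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- n + seq_len(m)
  is_basic <- c(rep(FALSE, n), rep(TRUE, m))

  run_phase <- function(cvec, xall, at_upper, basis, is_basic, phase) {
    iter <- 0L
    bland_after <- 20L * (n + m) + 100L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "iteration_limit", xall = xall,
                    at_upper = at_upper, basis = basis,
                    is_basic = is_basic))
      }
      Bm <- Aall[, basis, drop = FALSE]
      nb <- which(!is_basic)
      xall[basis] <- tryCatch(
        solve(Bm, b - Aall[, nb, drop = FALSE] %*% xall[nb]),
        error = function(e) rep(NA_real_, m))
      if (anyNA(xall[basis])) {
        return(list(status = "singular", xall = xall, at_upper = at_upper,
                    basis = basis, is_basic = is_basic))
      }
      y <- solve(t(Bm), cvec[basis])
      dnb <- cvec[nb] - as.vector(crossprod(Aall[, nb, drop = FALSE], y))
      free_nb <- uball[nb] - lball[nb] > tol   # fixed vars never enter
      enter_lo <- !at_upper[nb] & dnb > tol & free_nb
      enter_hi <- at_upper[nb] & dnb < -tol & free_nb
      cand <- which(enter_lo | enter_hi)
      if (!length(cand)) {
        return(list(status = "optimal", xall = xall, at_upper = at_upper,
                    basis = basis, is_basic = is_basic))
      }
      if (iter > bland_after) {
        j_rel <- cand[which.min(nb[cand])]
      } else {
        j_rel <- cand[which.max(abs(dnb[cand]))]
      }
      j <- nb[j_rel]
      dir <- if (at_upper[j]) -1 else 1
      w <- as.vector(solve(Bm, Aall[, j]))
      # x_B(t) = x_B - t * dir * w ; entering var moves by t * dir
      t_flip <- uball[j] - lball[j]
      t_best <- t_flip
      leave <- 0L
      leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        di <- dir * w[i]
        if (di > tol) {
          ti <- (xall[basis[i]] - lball[basis[i]]) / di
          if (ti < t_best - 1e-12 ||
              (ti < t_best + 1e-12 && leave > 0L &&
               abs(w[i]) > abs(w[leave]))) {
            t_best <- ti
            leave <- i
            leave_to_upper <- FALSE
          }
        } else if (di < -tol) {
          ti <- (uball[basis[i]] - xall[basis[i]]) / (-di)
          if (ti < t_best - 1e-12 ||
              (ti < t_best + 1e-12 && leave > 0L &&
               abs(w[i]) > abs(w[leave]))) {
            t_best <- ti
            leave <- i
            leave_to_upper <- TRUE
          }
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded", xall = xall, at_upper = at_upper,
                    basis = basis, is_basic = is_basic))
      }
      t_best <- max(t_best, 0)
      if (leave == 0L) {
        # bound flip, basis unchanged
        xall[j] <- if (at_upper[j]) lball[j] else uball[j]
        at_upper[j] <- !at_upper[j]
      } else {
        xall[basis] <- xall[basis] - t_best * dir * w
        xall[j] <- xall[j] + dir * t_best
        out <- basis[leave]
        xall[out] <- if (leave_to_upper) uball[out] else lball[out]
        at_upper[out] <- leave_to_upper
        is_basic[out] <- FALSE
        is_basic[j] <- TRUE
        basis[leave] <- j
      }
    }
  }

  # phase 1: maximize -sum(artificials)
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, xall, at_upper, basis, is_basic, 1L)
  if (ph1$status != "optimal") {
    st <- if (ph1$status == "unbounded") "infeasible" else ph1$status
    return(list(status = st, objective = NA_real_, x = rep(NA_real_, n)))
  }
  infeas <- sum(ph1$xall[n + seq_len(m)])
  scale <- max(1, max(abs(b)))
  if (infeas > feas_tol * scale) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  # pin artificials at zero for phase 2 (basic ones stay, harmlessly fixed)
  uball[n + seq_len(m)] <- 0
  xall <- ph1$xall
  xall[n + seq_len(m)] <- pmin(xall[n + seq_len(m)], 0)
  xall[n + seq_len(m)] <- pmax(xall[n + seq_len(m)], 0)

  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, xall, ph1$at_upper, ph1$basis, ph1$is_basic, 2L)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  x <- pmin(pmax(ph2$xall[seq_len(n)], lb), ub)
  list(status = "optimal", objective = sum(cc * x), x = x)
}
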