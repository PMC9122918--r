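# Linear-programming layer. All flux LPs in the package go through
# solve_lp(), a dense bounded-variable two-phase simplex (Bland's rule, so
# iterations are deterministic and cycling-free). Problem sizes here are a
# few dozen variables, so a dense implementation with a fresh basis solve
# per iteration is both fast enough and numerically transparent.

LP_BIG <- 1e6 # stand-in for infinite bounds; models should use finite bounds
LP_TOL <- 1e-9

#' Solve a bounded linear program
#'
#' Maximize (or minimize) `obj %*% v` subject to `Aeq %*% v = beq`,
#' `Aineq %*% v <= bineq` and `lb <= v <= ub`.
#'
#' @param obj objective coefficient vector.
#' @param Aeq,beq equality constraints (may be NULL).
#' @param Aineq,bineq inequality (<=) constraints (may be NULL).
#' @param lb,ub variable bounds; infinite entries are capped at +/- 1e6.
#' @param maximize logical.
#' @return list with `status` ("optimal" or "infeasible"), `solution`
#'   (variable values) and `objective`.
#' @keywords internal
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL, bineq = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  lb <- pmax(lb, -LP_BIG)
  ub <- pmin(ub, LP_BIG)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", solution = NULL, objective = NA_real_))
  }
  ub <- pmax(ub, lb)

  # slacks turn the inequalities into equalities
  n_sl <- if (is.null(Aineq)) 0L else nrow(Aineq)
  A <- rbind(
    if (!is.null(Aeq)) cbind(as.matrix(Aeq), matrix(0, nrow(Aeq), n_sl)),
    if (n_sl) cbind(as.matrix(Aineq), diag(n_sl))
  )
  b <- c(beq, bineq)
  l <- c(lb, rep(0, n_sl))
  u <- c(ub, rep(LP_BIG, n_sl))
  cost <- c(if (maximize) -obj else obj, rep(0, n_sl))

  res <- lp_simplex(cost, A, b, l, u)
  if (res$status != "optimal") {
    return(list(status = res$status, solution = NULL, objective = NA_real_))
  }
  v <- res$x[seq_len(n)]
  list(status = "optimal", solution = v, objective = sum(obj * v))
}

# Minimize cost %*% x subject to A x = b, l <= x <= u.
# Two-phase bounded-variable simplex with Bland's rule.
lp_simplex <- function(cost, A, b, l, u, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  # artificial variables give the phase-1 starting basis
  start <- ifelse(abs(l) <= abs(u), l, u) # nonbasic start at nearer bound
  r <- b - drop(A %*% start)
  art_sign <- ifelse(r >= 0, 1, -1)
  A_full <- cbind(A, diag(art_sign, m))
  l_full <- c(l, rep(0, m))
  u_full <- c(u, rep(LP_BIG, m))
  art <- n + seq_len(m)

  state <- list(
    basis = art,
    at_upper = rep(FALSE, n + m), # for nonbasic variables
    x = c(start, abs(r))
  )
  state$at_upper[seq_len(n)] <- start == u & l != u

  run_phase <- function(state, phase_cost) {
    for (iter in seq_len(max_iter)) {
      B <- A_full[, state$basis, drop = FALSE]
      Bi <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Bi)) {
        return(list(state = state, status = "singular"))
      }
      nonbasic <- setdiff(seq_len(n + m), state$basis)
      xb <- drop(Bi %*% (b - A_full[, nonbasic, drop = FALSE] %*%
        state$x[nonbasic]))
      state$x[state$basis] <- xb
      y <- drop(crossprod(Bi, phase_cost[state$basis]))
      d <- phase_cost[nonbasic] - drop(crossprod(A_full[, nonbasic,
        drop = FALSE
      ], y))
      # Bland: smallest-index eligible entering variable
      elig <- (!state$at_upper[nonbasic] & d < -LP_TOL &
        state$x[nonbasic] < u_full[nonbasic] - LP_TOL) |
        (state$at_upper[nonbasic] & d > LP_TOL &
          state$x[nonbasic] > l_full[nonbasic] + LP_TOL)
      if (!any(elig)) {
        return(list(state = state, status = "optimal"))
      }
      j <- nonbasic[which(elig)[1]]
      dir <- if (state$at_upper[j]) -1 else 1 # movement sign of x_j
      w <- drop(Bi %*% A_full[, j]) * dir # xB decreases by t*w
      t_own <- u_full[j] - l_full[j]
      t_best <- t_own
      leave <- 0L
      leave_to_upper <- FALSE
      for (k in seq_len(m)) {
        if (w[k] > LP_TOL) {
          tk <- (state$x[state$basis[k]] - l_full[state$basis[k]]) / w[k]
          if (tk < t_best - LP_TOL ||
            (tk < t_best + LP_TOL && (leave == 0L ||
              state$basis[k] < state$basis[leave]))) {
            t_best <- max(tk, 0)
            leave <- k
            leave_to_upper <- FALSE
          }
        } else if (w[k] < -LP_TOL) {
          tk <- (u_full[state$basis[k]] - state$x[state$basis[k]]) / (-w[k])
          if (tk < t_best - LP_TOL ||
            (tk < t_best + LP_TOL && (leave == 0L ||
              state$basis[k] < state$basis[leave]))) {
            t_best <- max(tk, 0)
            leave <- k
            leave_to_upper <- TRUE
          }
        }
      }
      if (!is.finite(t_best)) {
        return(list(state = state, status = "unbounded"))
      }
      # apply the step
      state$x[j] <- state$x[j] + dir * t_best
      state$x[state$basis] <- state$x[state$basis] - t_best * w
      if (leave == 0L) {
        # bound flip, basis unchanged
        state$at_upper[j] <- !state$at_upper[j]
      } else {
        out <- state$basis[leave]
        state$at_upper[out] <- leave_to_upper
        state$x[out] <- if (leave_to_upper) u_full[out] else l_full[out]
        state$basis[leave] <- j
      }
    }
    list(state = state, status = "maxiter")
  }

  # phase 1: drive the artificials to zero
  p1 <- run_phase(state, c(rep(0, n), rep(1, m)))
  if (p1$status != "optimal") {
    return(list(status = p1$status, x = NULL))
  }
  state <- p1$state
  if (sum(state$x[art]) > 1e-7) {
    return(list(status = "infeasible", x = NULL))
  }
  # phase 2: pin the artificials at zero and optimize the true cost
  u_full[art] <- 0
  state$x[art] <- pmin(state$x[art], 0)
  p2 <- run_phase(state, c(cost, rep(0, m)))
  if (p2$status != "optimal") {
    return(list(status = p2$status, x = NULL))
  }
  list(status = "optimal", x = p2$state$x[seq_len(n)])
}
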