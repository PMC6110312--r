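# Closed-form steady-state math for M targets competing for Ago-miRNA
# complexes, and the deterministic ODE integrator.

#' Michaelis--Menten constant of a miRNA target
#'
#' `K_M = (k_off + k_cat)/k_on`: the free-Ago concentration at which half of
#' a target's transcripts are miRNA-bound at steady state. Low `K_M` means a
#' high-affinity, strongly retained target.
#'
#' @param k_off dissociation rate (/h), `>= 0`.
#' @param k_cat bound-mRNA decay rate (/h), `>= 0`; `k_off + k_cat > 0`.
#' @param k_on binding rate (per molecule per h), `> 0`.
#' @return numeric, `K_M > 0`.
#' @examples
#' km_constant(k_off = 0.1, k_cat = 0.1, k_on = 0.2) # 1
#' @export
km_constant <- function(k_off, k_cat, k_on) {
  if (any(!is.finite(k_on) | k_on <= 0)) stopf("'k_on' must be > 0")
  if (any(k_off < 0) || any(k_cat < 0)) stopf("rates must be >= 0")
  if (any(k_off + k_cat <= 0)) stopf("'k_off + k_cat' must be > 0")
  (k_off + k_cat) / k_on
}

#' Fraction of target molecules bound to the miRNA
#'
#' At equilibrium the bound fraction of a target with constant `K_M` in a
#' cell with free Ago-miRNA level `A_free` is `f = 1/(1 + K_M/A_free)`,
#' strictly increasing in `A_free` with range `[0, 1)`.
#'
#' @param K_M Michaelis--Menten constant, `> 0`.
#' @param A_free free Ago-miRNA level, `>= 0`.
#' @return the bound fraction; `0` when `A_free = 0`.
#' @examples
#' bound_fraction(K_M = 1, A_free = 1) # 0.5
#' @export
bound_fraction <- function(K_M, A_free) {
  if (any(!is.finite(K_M) | K_M <= 0)) stopf("'K_M' must be > 0")
  if (any(A_free < 0)) stopf("'A_free' must be >= 0")
  # A_free/(A_free + K_M) is the 0-safe form of 1/(1 + K_M/A_free)
  A_free / (A_free + K_M)
}

#' Steady-state total level of a target at a given bound fraction
#'
#' `T* = T0 / (1 + f (T0/Tinf - 1))`: interpolates between the no-miRNA
#' level `T0` (at `f = 0`) and the saturating level `Tinf` (as `f -> 1`).
#'
#' @param T0 no-miRNA steady-state level, `> 0`.
#' @param Tinf saturating-miRNA level, `> 0`.
#' @param f bound fraction in `[0, 1)`.
#' @return steady-state total level.
#' @examples
#' target_steady_state(100, 25, 0)   # 100
#' target_steady_state(100, 25, 1/5) # 62.5 = (100 + 25)/2
#' @export
target_steady_state <- function(T0, Tinf, f) {
  if (any(!is.finite(T0) | T0 <= 0) || any(!is.finite(Tinf) | Tinf <= 0)) {
    stopf("'T0' and 'Tinf' must be > 0")
  }
  if (any(f < 0 | f >= 1)) stopf("'f' must be in [0, 1)")
  T0 / (1 + f * (T0 / Tinf - 1))
}

#' Critical free-Ago concentration of a target
#'
#' The unique free Ago-miRNA level at which a down-regulated target sits
#' exactly halfway between its extreme levels,
#' `T*(A_F^C) = (T0 + Tinf)/2`. Solving the halfway condition gives the
#' closed form `A_F^C = K_M * Tinf/T0`. Targets with `Tinf >= T0` (no
#' repression) are rejected: the halfway condition is vacuous for them.
#'
#' @inheritParams target_steady_state
#' @param K_M Michaelis--Menten constant, `> 0`.
#' @return the critical concentration `A_F^C > 0`.
#' @examples
#' critical_free_ago(K_M = 1, T0 = 100, Tinf = 25) # 0.25
#' @export
critical_free_ago <- function(K_M, T0, Tinf) {
  if (any(!is.finite(K_M) | K_M <= 0)) stopf("'K_M' must be > 0")
  if (any(!is.finite(T0) | T0 <= 0) || any(!is.finite(Tinf) | Tinf <= 0)) {
    stopf("'T0' and 'Tinf' must be > 0")
  }
  if (any(Tinf >= T0)) {
    stopf("degenerate target: 'Tinf' must be < 'T0' (no repression otherwise)")
  }
  K_M * Tinf / T0
}

#' One cell's steady state: free Ago and per-target free/bound mRNA
#'
#' @param A_total total Ago-miRNA level (>= 0).
#' @param A_free free Ago-miRNA level.
#' @param m per-target free mRNA.
#' @param Am per-target bound mRNA.
#' @param ids target labels.
#' @return an object of class `CellState`: a list with elements `A_total`,
#'   `A_free`, `m`, `Am`, `f` (bound fractions), all non-negative, with
#'   `A_free = A_total - sum(Am)` (conservation).
#' @export
cell_state <- function(A_total, A_free, m, Am, ids = NULL) {
  tot <- m + Am
  f <- ifelse(tot > 0, Am / tot, 0)
  if (!is.null(ids)) names(m) <- names(Am) <- names(f) <- ids
  structure(
    list(A_total = A_total, A_free = A_free, m = m, Am = Am, f = f),
    class = "CellState"
  )
}

#' @export
print.CellState <- function(x, ...) {
  cat(sprintf("<CellState> A_total = %.4g, A_free = %.4g, %d target(s)\n",
              x$A_total, x$A_free, length(x$m)))
  invisible(x)
}

#' Solve the competitive steady state of a cell
#'
#' With `M` targets competing for a conserved pool of `A_total` Ago-miRNA
#' complexes, the steady-state free level solves the scalar fixed point
#' `A_free = A_total - sum_i f_i(A_free) * T_i*(A_free)`, with `f_i` from
#' [bound_fraction()] and `T_i*` from [target_steady_state()]. The left side
#' is increasing and the bound mass decreasing in `A_free`, so the solution
#' is unique; it is found by bracketed bisection on `[0, A_total]`, run to
#' (near) machine precision because the bound mass can change steeply with
#' `A_free` near the titration threshold.
#'
#' @param params a [target_params()] table.
#' @param A_total total Ago-miRNA level, `>= 0`.
#' @param tol relative tolerance of the root (default `1e-10`).
#' @return a [cell_state()] at steady state.
#' @examples
#' p <- target_params(10, 0.1, 0.2, 0.1, 0.4)
#' solve_free_ago(p, A_total = 50)
#' @export
solve_free_ago <- function(params, A_total, tol = 1e-10) {
  validate_target_params(params)
  if (!is.finite(A_total) || A_total < 0) stopf("'A_total' must be >= 0")
  if (A_total == 0) {
    return(cell_state(0, 0, m = params$T0, Am = rep(0, nrow(params)),
                      ids = params$id))
  }
  bound_mass <- function(A) {
    f <- A / (A + params$K_M)
    sum(f * params$T0 / (1 + f * (params$T0 / params$Tinf - 1)))
  }
  g <- function(A) A + bound_mass(A) - A_total
  # g is strictly increasing with g(0) <= 0 <= g(A_total): bisect to
  # machine precision (the titration curve can be very steep, so an
  # x-tolerance alone leaves large residuals in g)
  lo <- 0
  hi <- A_total
  for (iter in 1:110) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo <= tol * 1e-4 * max(A_total, 1)) break
  }
  A_free <- (lo + hi) / 2
  f <- A_free / (A_free + params$K_M)
  Tstar <- params$T0 / (1 + f * (params$T0 / params$Tinf - 1))
  st <- cell_state(A_total, A_free, m = (1 - f) * Tstar, Am = f * Tstar,
                   ids = params$id)
  resid <- abs(A_free + sum(st$Am) - A_total)
  if (resid > 1e-6 * max(A_total, 1)) {
    stopf("fixed-point solver did not converge (residual %.3g)", resid)
  }
  st
}

#' Integrate the kinetic ODE system of a cell
#'
#' Numerically integrates the `2M` ordinary differential equations of the
#' competing-target model at constant total Ago-miRNA `A`:
#' `dm_i/dt = alpha_i - delta_i m_i - k_on_i m_i A_free + k_off_i Am_i`,
#' `dAm_i/dt = k_on_i m_i A_free - (k_off_i + k_cat_i) Am_i`, with
#' `A_free = A - sum_j Am_j`. At large times the trajectory converges to the
#' [solve_free_ago()] steady state, and `A_free + sum(Am) = A_total` holds
#' identically along the trajectory.
#'
#' @param params a [target_params()] table.
#' @param A_total total Ago-miRNA level.
#' @param init a [cell_state()] giving initial `m` and `Am` (defaults to the
#'   empty cell: `m = 0`, `Am = 0`).
#' @param t_grid increasing vector of output times (h).
#' @param ... passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return a `data.frame` with columns `time`, `A_free`, and `m.<id>`,
#'   `Am.<id>` per target.
#' @export
integrate_ode <- function(params, A_total, init = NULL,
                          t_grid = seq(0, 100, by = 1), ...) {
  validate_target_params(params)
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stopf("'t_grid' must be strictly increasing")
  }
  M <- nrow(params)
  if (is.null(init)) {
    y0 <- c(rep(0, M), rep(0, M))
  } else {
    if (any(init$m < 0) || any(init$Am < 0)) stopf("negative initial state")
    y0 <- c(init$m, init$Am)
  }
  deriv <- function(t, y, parms) {
    m <- y[seq_len(M)]
    Am <- y[M + seq_len(M)]
    A_free <- A_total - sum(Am)
    dm <- params$alpha - params$delta * m - params$k_on * m * A_free +
      params$k_off * Am
    dAm <- params$k_on * m * A_free - (params$k_off + params$k_cat) * Am
    list(c(dm, dAm))
  }
  sol <- deSolve::ode(y = y0, times = t_grid, func = deriv, parms = NULL, ...)
  if (attr(sol, "istate")[1] < 0) stopf("ODE integration failed")
  out <- as.data.frame(sol)
  names(out) <- c("time", paste0("m.", params$id), paste0("Am.", params$id))
  out$A_free <- A_total - rowSums(out[, M + 1 + seq_len(M), drop = FALSE])
  out
}
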