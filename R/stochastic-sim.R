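# Stochastic simulation of the competing-target reaction network: exact SSA
# and tau-leaping with a bounded-relative-change step rule. The total Ago
# pool is conserved structurally: the state tracks (m_i, Am_i) and
# A_free = A_total - sum(Am) is derived, so conservation holds at every event.

#' Mass-action propensities of the competing-target network
#'
#' The network has five reactions per target i: production (`alpha_i`), free
#' decay (`delta_i * m_i`), binding (`k_on_i * m_i * A_free`), unbinding
#' (`k_off_i * Am_i`) and catalyzed decay (`k_cat_i * Am_i`).
#'
#' @param state a [cell_state()] with non-negative copy numbers.
#' @param params a [target_params()] table.
#' @return numeric matrix `M x 5` with columns `prod`, `decay`, `bind`,
#'   `unbind`, `cat`; all entries non-negative.
#' @export
propensities <- function(state, params) {
  if (any(state$m < 0) || any(state$Am < 0) || state$A_free < 0) {
    stopf("negative copy number in state")
  }
  cbind(
    prod = params$alpha,
    decay = params$delta * state$m,
    bind = params$k_on * state$m * state$A_free,
    unbind = params$k_off * state$Am,
    cat = params$k_cat * state$Am
  )
}

# Internal propensity on raw vectors (hot path)
prop_raw <- function(m, Am, A_free, params) {
  cbind(params$alpha,
        params$delta * m,
        params$k_on * m * A_free,
        params$k_off * Am,
        params$k_cat * Am)
}

# One exact SSA step; returns list(m, Am, t_next) or NULL if no reaction can
# fire (total propensity zero).
ssa_step <- function(m, Am, A_total, params, t) {
  a <- prop_raw(m, Am, A_total - sum(Am), params)
  a0 <- sum(a)
  if (a0 <= 0) return(NULL)
  dt <- stats::rexp(1, a0)
  k <- sample.int(length(a), 1, prob = as.vector(a))
  M <- nrow(params)
  i <- (k - 1) %% M + 1
  r <- (k - 1) %/% M + 1
  if (r == 1) m[i] <- m[i] + 1
  else if (r == 2) m[i] <- m[i] - 1
  else if (r == 3) { m[i] <- m[i] - 1; Am[i] <- Am[i] + 1 }
  else if (r == 4) { m[i] <- m[i] + 1; Am[i] <- Am[i] - 1 }
  else Am[i] <- Am[i] - 1
  list(m = m, Am = Am, t = t + dt)
}

# Tau selection: bounded relative change (epsilon) on m, Am and A_free.
select_tau <- function(m, Am, A_free, a, params, epsilon) {
  # Net drift and diffusion per species from reaction propensities
  mu_m <- a[, 1] - a[, 2] - a[, 3] + a[, 4]
  s2_m <- a[, 1] + a[, 2] + a[, 3] + a[, 4]
  mu_Am <- a[, 3] - a[, 4] - a[, 5]
  s2_Am <- a[, 3] + a[, 4] + a[, 5]
  mu_A <- -sum(a[, 3]) + sum(a[, 4]) + sum(a[, 5])
  s2_A <- sum(a[, 3] + a[, 4] + a[, 5])
  bnd <- function(x, mu, s2) {
    g <- pmax(epsilon * x, 1)
    min(ifelse(abs(mu) > 0, g / abs(mu), Inf),
        ifelse(s2 > 0, g^2 / s2, Inf))
  }
  min(bnd(m, mu_m, s2_m), bnd(Am, mu_Am, s2_Am), bnd(A_free, mu_A, s2_A))
}

# Simulate one trajectory, returning samples of (m, Am) on a uniform grid.
simulate_trajectory <- function(params, A_total, duration, burn_in,
                                method = c("tau_leap", "ssa"),
                                sample_dt = 1, epsilon = 0.03,
                                init = NULL) {
  method <- match.arg(method)
  M <- nrow(params)
  A_total <- round(A_total) # discrete copy numbers: A_free must stay integer
  if (is.null(init)) {
    # start at the rounded deterministic steady state: the burn-in then only
    # has to absorb the rounding, not the full titration relaxation (which
    # is slow near the threshold)
    st <- solve_free_ago(params, A_total)
    m <- round(st$m)
    Am <- round(st$Am)
    while (sum(Am) > A_total) Am[which.max(Am)] <- Am[which.max(Am)] - 1
  } else {
    m <- init$m
    Am <- init$Am
  }
  if (sum(Am) > A_total) stopf("initial bound mRNA exceeds 'A_total'")
  grid <- seq(burn_in + sample_dt, duration, by = sample_dt)
  samples_m <- matrix(NA_real_, length(grid), M)
  samples_Am <- matrix(NA_real_, length(grid), M)
  t <- 0
  gi <- 1L
  n_fallback <- 0L
  while (gi <= length(grid)) {
    if (method == "ssa") {
      stp <- ssa_step(m, Am, A_total, params, t)
      t_next <- if (is.null(stp)) Inf else stp$t
      while (gi <= length(grid) && grid[gi] <= t_next) {
        samples_m[gi, ] <- m
        samples_Am[gi, ] <- Am
        gi <- gi + 1L
      }
      if (is.null(stp)) break
      m <- stp$m
      Am <- stp$Am
      t <- stp$t
    } else {
      A_free <- A_total - sum(Am)
      a <- prop_raw(m, Am, A_free, params)
      a0 <- sum(a)
      if (a0 <= 0) {
        samples_m[gi:length(grid), ] <- rep(m, each = length(grid) - gi + 1)
        samples_Am[gi:length(grid), ] <- rep(Am, each = length(grid) - gi + 1)
        break
      }
      tau <- min(select_tau(m, Am, A_free, a, params, epsilon),
                 grid[gi] - t + sample_dt)
      if (tau < 2 / a0) {
        # leap would be smaller than a few exact events: exact stepping
        stp <- ssa_step(m, Am, A_total, params, t)
        n_fallback <- n_fallback + 1L
        t_next <- stp$t
        while (gi <= length(grid) && grid[gi] <= t_next) {
          samples_m[gi, ] <- m
          samples_Am[gi, ] <- Am
          gi <- gi + 1L
        }
        m <- stp$m
        Am <- stp$Am
        t <- t_next
        next
      }
      repeat {
        k <- matrix(stats::rpois(length(a), as.vector(a) * tau), nrow = M)
        m_new <- m + k[, 1] - k[, 2] - k[, 3] + k[, 4]
        Am_new <- Am + k[, 3] - k[, 4] - k[, 5]
        if (all(m_new >= 0) && all(Am_new >= 0) && sum(Am_new) <= A_total) {
          break
        }
        tau <- tau / 2
        n_fallback <- n_fallback + 1L
        if (tau < 10 / a0) {
          stp <- ssa_step(m, Am, A_total, params, t)
          m_new <- stp$m
          Am_new <- stp$Am
          tau <- stp$t - t
          break
        }
      }
      t_next <- t + tau
      while (gi <= length(grid) && grid[gi] <= t_next) {
        samples_m[gi, ] <- m
        samples_Am[gi, ] <- Am
        gi <- gi + 1L
      }
      m <- m_new
      Am <- Am_new
      t <- t_next
    }
  }
  list(m = samples_m, Am = samples_Am, grid = grid, n_fallback = n_fallback)
}

#' Stochastic simulation of one cell
#'
#' Runs `n_replicates` independent stochastic trajectories of the
#' competing-target network at fixed total Ago-miRNA `A_total`, discards a
#' burn-in segment, samples the state on a uniform time grid and returns
#' time-averaged means and standard deviations per species. Replicates use
#' sub-seeds derived deterministically from `seed`, so identical seeds give
#' identical ensembles. Tau-leaping falls back to exact stepping whenever a
#' leap would be too small or would drive a population negative; the number
#' of fallbacks is recorded.
#'
#' @param params a [target_params()] table.
#' @param A_total total Ago-miRNA copy number (integer-valued, `>= 0`).
#' @param duration total simulated time per replicate (time units).
#' @param burn_in initial segment discarded before averaging
#'   (`0 <= burn_in < duration`).
#' @param n_replicates number of independent trajectories (`>= 1`).
#' @param seed integer master seed.
#' @param method `"tau_leap"` (default) or `"ssa"` (exact).
#' @param sample_dt spacing of the sampling grid (default 1 time unit).
#' @param epsilon tau-leap bounded-relative-change parameter (default 0.03).
#' @return an object of class `SimulationEnsemble`: a `data.frame` with one
#'   row per species (`m.<id>`, `Am.<id>`, `T.<id>` = total, `A_free`) and
#'   columns `mean`, `sd` (pooled over post-burn-in samples of all
#'   replicates), `se_mean` (SE of the replicate means); attributes record
#'   the protocol (`n_replicates`, `duration`, `burn_in`, `seed`, `method`,
#'   `n_fallback`).
#' @examples
#' p <- target_params(10, 0.1, 0.2, 0.1, 0.4)
#' simulate_cell(p, A_total = 20, duration = 200, burn_in = 50,
#'               n_replicates = 2, seed = 1)
#' @export
simulate_cell <- function(params, A_total, duration = 1e5, burn_in = 1e4,
                          n_replicates = 6, seed = 1,
                          method = c("tau_leap", "ssa"),
                          sample_dt = 1, epsilon = 0.03) {
  method <- match.arg(method)
  validate_target_params(params)
  if (A_total < 0) stopf("'A_total' must be >= 0")
  if (!(burn_in >= 0 && burn_in < duration)) {
    stopf("need 0 <= burn_in < duration")
  }
  if (n_replicates < 1) stopf("'n_replicates' must be >= 1")
  M <- nrow(params)
  rep_means <- vector("list", n_replicates)
  acc_sum <- 0
  acc_sq <- 0
  acc_n <- 0
  n_fallback <- 0L
  for (r in seq_len(n_replicates)) {
    tr <- with_seed(derive_seed(seed, r), {
      simulate_trajectory(params, A_total, duration, burn_in,
                          method = method, sample_dt = sample_dt,
                          epsilon = epsilon)
    })
    species <- cbind(tr$m, tr$Am, tr$m + tr$Am,
                     A_total - rowSums(tr$Am[, seq_len(M), drop = FALSE]))
    rep_means[[r]] <- colMeans(species)
    acc_sum <- acc_sum + colSums(species)
    acc_sq <- acc_sq + colSums(species^2)
    acc_n <- acc_n + nrow(species)
    n_fallback <- n_fallback + tr$n_fallback
  }
  mu <- acc_sum / acc_n
  sd_pooled <- sqrt(pmax(acc_sq / acc_n - mu^2, 0) * acc_n / max(acc_n - 1, 1))
  rm <- do.call(rbind, rep_means)
  se_mean <- if (n_replicates > 1) {
    apply(rm, 2, stats::sd) / sqrt(n_replicates)
  } else {
    rep(NA_real_, ncol(rm))
  }
  out <- data.frame(
    species = c(paste0("m.", params$id), paste0("Am.", params$id),
                paste0("T.", params$id), "A_free"),
    mean = mu, sd = sd_pooled, se_mean = se_mean,
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("SimulationEnsemble", "data.frame"),
            n_replicates = n_replicates, duration = duration,
            burn_in = burn_in, seed = seed, method = method,
            sample_dt = sample_dt, n_fallback = n_fallback)
}

#' Stochastic snapshots of a virtual cell population
#'
#' Simulates one stochastic trajectory per cell (each with its own
#' `A_total`) and records the state at the end of the run as that cell's
#' expression snapshot -- a single-cell "measurement" carrying the intrinsic
#' noise of the kinetics. Used for the windowed noise/correlation analyses.
#'
#' @inheritParams simulate_cell
#' @param A_cells numeric vector of per-cell total Ago-miRNA levels.
#' @return an [expression_matrix()] of total target levels (`m + Am`) with
#'   `proxy = A_cells`.
#' @export
simulate_population <- function(params, A_cells, duration = 500,
                                burn_in = 100, seed = 1,
                                method = c("tau_leap", "ssa"),
                                sample_dt = 1, epsilon = 0.03) {
  method <- match.arg(method)
  validate_target_params(params)
  vals <- matrix(NA_real_, length(A_cells), nrow(params))
  for (j in seq_along(A_cells)) {
    tr <- with_seed(derive_seed(seed, j), {
      simulate_trajectory(params, A_cells[j], duration, burn_in,
                          method = method, sample_dt = sample_dt,
                          epsilon = epsilon)
    })
    last <- nrow(tr$m)
    vals[j, ] <- tr$m[last, ] + tr$Am[last, ]
  }
  expression_matrix(vals,
                    proxy = A_cells,
                    cell_ids = paste0("cell", seq_along(A_cells)),
                    gene_ids = params$id)
}
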