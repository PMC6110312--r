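# Independent oracles and small fixtures shared across the suite.

# Brute-force bisection for the steady-state free-Ago fixed point
# A_free = A_total - sum_i f_i(A_free) T_i*(A_free); independent of the
# package's solver (works from the raw rates).
bisect_free_ago <- function(params, A_total, tol = 1e-12) {
  g <- function(A) {
    f <- A / (A + (params$k_off + params$k_cat) / params$k_on)
    T0 <- params$alpha / params$delta
    Tinf <- params$alpha / params$k_cat
    A + sum(f * T0 / (1 + f * (T0 / Tinf - 1))) - A_total
  }
  lo <- 0
  hi <- A_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(A_total, 1)) break
  }
  (lo + hi) / 2
}

# Bisection for the free-Ago level at which a single target sits halfway
# between T0 and Tinf (the halfway condition solved numerically).
bisect_halfway <- function(K_M, T0, Tinf, tol = 1e-14) {
  level <- function(A) {
    f <- A / (A + K_M)
    T0 / (1 + f * (T0 / Tinf - 1))
  }
  half <- (T0 + Tinf) / 2
  lo <- 0
  hi <- K_M
  while (level(hi) > half) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (level(mid) > half) lo <- mid else hi <- mid
    if (hi - lo < tol * max(K_M, 1)) break
  }
  (lo + hi) / 2
}

# Small benchmark used where the full 300 x 4000 problem would be overkill.
small_spec <- function(seed = 1, M = 40, N = 600, noise_sd = NULL) {
  benchmark_spec(M = M, N = N, noise_sd = noise_sd, seed = seed)
}

small_config <- function(...) {
  inference_config(n_low = 240, n_high = 30, ...)
}

# Toy panel with hand-picked K_M pools for the ceRNA scenarios. The
# high-K_M (weakly retained) targets decay fast when bound (large k_cat,
# which also raises their K_M), so they have the deeper maximal repression
# and the most to regain when a sponge soaks up the miRNA.
toy_cerna_background <- function() {
  target_params(
    alpha = rep(20, 6),
    delta = rep(0.1, 6),
    k_on = c(40, 40, 40, 0.05, 0.05, 0.05),
    k_off = c(0.1, 0.2, 0.15, 0.1, 0.2, 0.3),
    k_cat = c(0.15, 0.16, 0.15, 0.8, 0.9, 0.8),
    id = paste0("g", 1:6)
  )
}
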