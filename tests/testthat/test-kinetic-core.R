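test_that("Michaelis-Menten constant and bound fraction follow the closed forms", {
  expect_equal(km_constant(k_off = 0.1, k_cat = 0.1, k_on = 0.2), 1)
  expect_equal(km_constant(k_off = 0, k_cat = 0.2, k_on = 0.2), 1)
  expect_error(km_constant(0.1, 0.1, 0), "k_on")
  expect_error(km_constant(0, 0, 0.2), "k_off \\+ k_cat")

  expect_equal(bound_fraction(K_M = 1, A_free = 1), 0.5)
  expect_equal(bound_fraction(K_M = 1, A_free = 0), 0)
  expect_equal(bound_fraction(K_M = 1, A_free = 3), 0.75)
  expect_error(bound_fraction(-1, 1))
  expect_error(bound_fraction(1, -1))

  # strictly increasing in A_free, range [0, 1)
  a <- seq(0, 100, length.out = 200)
  f <- bound_fraction(2.5, a)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))

  # with k_on fixed at 0.2, K_M <= 0.02 forces k_off + k_cat <= 0.004
  expect_true(km_constant(0.002, 0.002, 0.2) <= 0.02)
  expect_gt(km_constant(0.003, 0.002, 0.2), 0.02)
})

test_that("steady-state level interpolates between T0 and Tinf", {
  expect_equal(target_steady_state(100, 25, 0), 100)
  expect_equal(target_steady_state(100, 25, 1 / 5), 62.5)
  expect_equal(target_steady_state(100, 25, 2 / 3), 100 / 3)
  expect_error(target_steady_state(100, 25, 1), "f")
  expect_error(target_steady_state(100, 25, -0.1), "f")

  # monotone decreasing in f for a repressed target; limits at f -> 0, 1
  f <- seq(0, 0.999, length.out = 300)
  tt <- target_steady_state(100, 25, f)
  expect_true(all(diff(tt) < 0))
  expect_equal(tt[1], 100)
  expect_lt(abs(tail(tt, 1) - 25), 0.1)
})

test_that("critical free-Ago matches the bisection oracle and halfway identity", {
  expect_equal(critical_free_ago(1, 100, 25), 0.25)
  expect_equal(critical_free_ago(2, 200, 100), 1)
  expect_error(critical_free_ago(1, 100, 100), "degenerate")

  # halfway identity + oracle agreement on random triples
  set.seed(42)
  for (i in 1:100) {
    K_M <- exp(runif(1, -5, 5))
    T0 <- exp(runif(1, 1, 8))
    Tinf <- T0 * runif(1, 0.05, 0.95)
    afc <- critical_free_ago(K_M, T0, Tinf)
    lvl <- target_steady_state(T0, Tinf, bound_fraction(K_M, afc))
    expect_lt(abs(lvl - (T0 + Tinf) / 2) / ((T0 + Tinf) / 2), 1e-12)
    expect_lt(abs(afc - bisect_halfway(K_M, T0, Tinf)) / afc, 1e-8)
  }

  # A_F^C scales linearly with K_M
  expect_equal(critical_free_ago(4, 100, 25), 4 * critical_free_ago(1, 100, 25))
})

test_that("competitive steady-state solver agrees with an independent bisection", {
  p1 <- target_params(10, 0.1, 0.2, 0.1, 0.4)
  st <- solve_free_ago(p1, 80)
  expect_lt(abs(st$A_free - bisect_free_ago(p1, 80)), 1e-8)

  set.seed(7)
  for (i in 1:100) {
    M <- sample(1:5, 1)
    p <- target_params(
      alpha = exp(runif(M, 0, 4)), delta = exp(runif(M, -3, 0)),
      k_on = exp(runif(M, -3, 1)), k_off = exp(runif(M, -3, 0)),
      k_cat = exp(runif(M, -2, 1))
    )
    A <- exp(runif(1, -2, 8))
    st <- solve_free_ago(p, A)
    expect_lt(abs(st$A_free - bisect_free_ago(p, A)) / max(A, 1), 1e-8)
    # conservation and consistency of the returned state
    expect_lt(abs(st$A_free + sum(st$Am) - A), 1e-6 * max(A, 1))
    expect_true(all(st$m >= 0) && all(st$Am >= 0))
  }
})

test_that("no-miRNA and saturation limits of the solver", {
  p <- target_params(c(10, 4), c(0.1, 0.2), 0.2, 0.1, c(0.4, 0.5))
  st0 <- solve_free_ago(p, 0)
  expect_equal(st0$A_free, 0)
  expect_equal(unname(st0$m), p$T0)
  expect_equal(unname(st0$Am), c(0, 0))

  # A_total >> sum(Tinf): nearly all targets bound, A_free -> A - sum(Tinf)
  A <- 1e6
  st <- solve_free_ago(p, A)
  expect_lt(abs(st$A_free - (A - sum(p$Tinf))) / A, 1e-3)
})

test_that("ODE integration relaxes to the fixed point and conserves total Ago", {
  p <- target_params(c(10, 4), c(0.1, 0.2), 0.2, 0.1, c(0.4, 0.5))

  # birth-death relaxation with no miRNA
  tr0 <- integrate_ode(p, A_total = 0, t_grid = seq(0, 200, 2))
  expect_lt(abs(tail(tr0$m.t1, 1) - p$T0[1]) / p$T0[1], 1e-4)
  expect_lt(abs(tail(tr0$m.t2, 1) - p$T0[2]) / p$T0[2], 1e-4)

  A <- 60
  tr <- integrate_ode(p, A, t_grid = seq(0, 600, 2), rtol = 1e-10, atol = 1e-10)
  st <- solve_free_ago(p, A)
  end_total <- tail(tr$m.t1 + tr$Am.t1, 1)
  expect_lt(abs(end_total - (st$m[1] + st$Am[1])) / (st$m[1] + st$Am[1]), 1e-6)
  expect_lt(abs(tail(tr$A_free, 1) - st$A_free) / st$A_free, 1e-5)

  # conservation at every output point (structural in this parameterization)
  expect_lt(max(abs(A - tr$A_free - tr$Am.t1 - tr$Am.t2)), 1e-8 * A)
  expect_error(integrate_ode(p, 10, t_grid = c(0, 0, 1)), "increasing")
})

test_that("parameter tables validate and round-trip through TSV", {
  p <- target_params(c(10, 20), 0.1, 0.2, 0.1, 0.4)
  expect_s3_class(p, "TargetParams")
  expect_equal(p$T0, c(100, 200))
  expect_equal(p$K_M, c(2.5, 2.5))
  expect_error(target_params(-1, 0.1, 0.2, 0.1, 0.4), "alpha")
  expect_error(target_params(10, 0.1, 0.2, -0.1, 0.4), "k_off")

  tf <- tempfile(fileext = ".tsv")
  write_target_params(p, tf)
  p2 <- read_target_params(tf)
  expect_equal(p2$alpha, p$alpha)
  expect_equal(p2$K_M, p$K_M)
  unlink(tf)
})
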