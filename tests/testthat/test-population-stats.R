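make_stat_matrix <- function(n_cells = 120, seed = 1) {
  # two "targets" responding to the proxy plus flat background genes
  set.seed(seed)
  proxy <- 2^seq(0, 10, length.out = n_cells)
  t1 <- 100 / (1 + proxy / 30) * exp(rnorm(n_cells, 0, 0.1))
  t2 <- 50 / (1 + proxy / 50) * exp(rnorm(n_cells, 0, 0.1))
  bg <- sapply(1:6, function(i) 40 * exp(rnorm(n_cells, 0, 0.1)))
  vals <- cbind(t1 = t1, t2 = t2, bg)
  colnames(vals) <- c("t1", "t2", paste0("b", 1:6))
  expression_matrix(vals, proxy = proxy)
}

test_that("sliding CV is self-normalizing and respects its window contract", {
  em <- make_stat_matrix()
  expect_error(sliding_cv(em, "t1", c("t1", "b1"), window = 40), "disjoint")
  expect_error(sliding_cv(em, "t1", "b1", window = 1000), "window")

  # target set = background set: log2 ratio identically zero
  cv0 <- sliding_cv(em, c("t1", "t2"), c("t1", "t2"), window = 40)
  expect_true(all(abs(cv0$value) < 1e-12))
  expect_equal(nrow(cv0), 120)
  expect_true(all(cv0$se >= 0, na.rm = TRUE))

  # responding targets are noisier than flat background near their threshold
  cv <- sliding_cv(em, c("t1", "t2"), paste0("b", 1:6), window = 40)
  expect_gt(max(cv$value), 0)
})

test_that("pairwise correlation curves detect co-regulation against background", {
  em <- make_stat_matrix(seed = 2)
  # duplicated genes correlate perfectly in every window
  dup <- expression_matrix(cbind(g1 = em$values[, "t1"], g2 = em$values[, "t1"],
                                 em$values[, 3:8]),
                           proxy = em$proxy)
  pc_dup <- sliding_pairwise_correlation(dup, c("g1", "g2"), paste0("b", 1:6),
                                         window = 40, n_background_draws = 5,
                                         step = 10)
  expect_true(all(abs(pc_dup$target_r - 1) < 1e-12))

  # independent noise genes: windowed mean r stays near zero
  set.seed(3)
  noise <- expression_matrix(
    matrix(exp(rnorm(150 * 8)), 150, 8,
           dimnames = list(NULL, c(paste0("n", 1:4), paste0("b", 1:4)))),
    proxy = seq_len(150)
  )
  pc0 <- sliding_pairwise_correlation(noise, paste0("n", 1:4), paste0("b", 1:4),
                                      window = 60, n_background_draws = 5,
                                      step = 15)
  expect_true(all(abs(pc0$target_r) < 3 / sqrt(60)))

  # co-regulated sigmoids correlate above their background somewhere
  pc <- sliding_pairwise_correlation(em, c("t1", "t2"), paste0("b", 1:6),
                                     window = 40, n_background_draws = 10,
                                     step = 5, seed = 4)
  expect_gt(max(pc$target_r, na.rm = TRUE), 0.3)
})

test_that("target panels are score-ranked and filtered on expression and repression", {
  scores <- data.frame(target = paste0("g", 1:5), score = c(5, 4, 3, 2, 1))
  refs <- data.frame(
    target = paste0("g", 1:5),
    T0 = c(100, 100, 5, 100, 100),
    Tinf = c(50, 99, 2, 80, 95.5)
  )
  # g1: strong repression, kept; g2: log2 ratio -0.014 > -0.12, out;
  # g3: T0 below floor, out; g4: -0.32, kept; g5: -0.065, out
  panel <- select_targets(scores, refs, top_n = 10)
  expect_equal(panel$target, c("g1", "g4"))

  # boundary: at least 8% down-regulation corresponds to -0.12 in log2
  refs2 <- data.frame(target = c("a", "b"), T0 = c(100, 100),
                      Tinf = c(100 * 2^-0.13, 100 * 2^-0.11))
  panel2 <- select_targets(data.frame(target = c("a", "b"), score = 1:2), refs2)
  expect_equal(panel2$target, "a")

  refs3 <- data.frame(target = "up", T0 = 100, Tinf = 150)
  expect_error(select_targets(data.frame(target = "up", score = 1), refs3),
               "empty panel")
  # top_n truncates after ranking
  panel3 <- select_targets(scores, refs, top_n = 1)
  expect_equal(panel3$target, "g1")
})

test_that("fold-change-by-rank curves are exact running means", {
  fc <- c(a = -1, b = -0.5, c = -2, d = 0.2)
  key <- c(a = 10, b = 5, c = 20, d = 1) # e.g. inferred K_M, descending
  curve <- fold_change_by_rank(fc, key, direction = "desc")
  expect_equal(curve$target, c("c", "a", "b", "d"))
  expect_equal(curve$mean_log2_fc,
               cumsum(c(-2, -1, -0.5, 0.2)) / 1:4)

  # ranking by the fold change itself: running mean is non-decreasing
  curve2 <- fold_change_by_rank(fc, fc, direction = "asc")
  expect_true(all(diff(curve2$mean_log2_fc) >= 0))

  expect_error(fold_change_by_rank(fc, 1:2), "align")
})

test_that("ranking by true affinity concentrates the strongest repression", {
  spec <- small_spec(seed = 11, M = 60, N = 400, noise_sd = 0.3)
  params <- draw_target_params(spec)
  fc <- setNames(log2(params$Tinf / params$T0), params$id)
  # high-K_M targets decay fastest when bound (k_cat enters both), so the
  # K_M-ranked running mean beats the random expectation (= overall mean)
  by_km <- fold_change_by_rank(fc, params$K_M, direction = "desc")
  expect_lt(by_km$mean_log2_fc[20], mean(fc))
  expect_equal(by_km$n_top, 1:60)
  # the full-panel mean is ranking-invariant
  expect_equal(by_km$mean_log2_fc[60], mean(fc))
})
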