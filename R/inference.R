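# Rank-1 inference of per-cell free Ago-miRNA and per-target K_M from a
# noisy cell-by-target matrix: reference-level estimation, responsive-cell
# selection, two-pass smoothing, the tilde transform, SVD factorization and
# the averaging refinement of K_M.

#' Estimate per-target reference levels from extreme-proxy cells
#'
#' `T0_i` is the mean expression of target `i` over the `n_low` cells with
#' the lowest proxy (effectively miRNA-free) and `Tinf_i` the mean over the
#' `n_high` cells with the highest proxy (saturating miRNA). Alternatively,
#' for real data, explicit proxy cutoffs can define the two pools (e.g.
#' proxy `== 0` for the `T0` pool and proxy `> 6.8` for the `Tinf` pool).
#' Targets with `T0 <= Tinf` (not observably repressed) are dropped. A
#' safety margin `c_i = margin_fraction * (T0_i - Tinf_i)` is attached; the
#' smoothing stage keeps every entry inside `(Tinf_i + c_i, T0_i - c_i)` so
#' the tilde transform never divides by a vanishing difference.
#'
#' @param mat an [expression_matrix()].
#' @param n_low,n_high pool sizes (defaults 1600 and 200, the synthetic
#'   benchmark's counts); ignored when proxy cutoffs are given.
#' @param margin_fraction fraction of `T0 - Tinf` used as safety margin
#'   (default 0.10).
#' @param proxy_low,proxy_high optional proxy cutoffs: cells with
#'   `proxy <= proxy_low` form the `T0` pool and `proxy > proxy_high` the
#'   `Tinf` pool.
#' @return a `data.frame` of class `ReferenceLevels` with columns `target`,
#'   `T0`, `Tinf`, `margin`; attribute `dropped` lists discarded targets.
#' @export
estimate_reference_levels <- function(mat, n_low = 1600, n_high = 200,
                                      margin_fraction = 0.10,
                                      proxy_low = NULL, proxy_high = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  N <- nrow(mat$values)
  if (is.null(proxy_low) && is.null(proxy_high)) {
    if (n_low + n_high >= N) stopf("'n_low + n_high' must be < cell count")
    o <- order(mat$proxy)
    low <- o[seq_len(n_low)]
    high <- o[seq.int(N - n_high + 1L, N)]
  } else {
    if (is.null(proxy_low) || is.null(proxy_high)) {
      stopf("give both 'proxy_low' and 'proxy_high' or neither")
    }
    low <- which(mat$proxy <= proxy_low)
    high <- which(mat$proxy > proxy_high)
    if (length(low) == 0 || length(high) == 0) {
      stopf("empty reference pool under the given proxy cutoffs")
    }
  }
  T0 <- colMeans(mat$values[low, , drop = FALSE])
  Tinf <- colMeans(mat$values[high, , drop = FALSE])
  keep <- T0 > Tinf & Tinf > 0
  if (!any(keep)) stopf("all targets dropped: no target with T0 > Tinf > 0")
  dropped <- colnames(mat$values)[!keep]
  if (length(dropped) > 0) {
    message(sprintf("reference levels: dropped %d target(s) with T0 <= Tinf",
                    length(dropped)))
  }
  refs <- data.frame(
    target = colnames(mat$values)[keep],
    T0 = T0[keep], Tinf = Tinf[keep],
    margin = margin_fraction * (T0[keep] - Tinf[keep]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(refs) <- c("ReferenceLevels", "data.frame")
  attr(refs, "dropped") <- dropped
  attr(refs, "margin_fraction") <- margin_fraction
  refs
}

#' Select the responsive cells along the miRNA gradient
#'
#' Sorts cells by proxy, computes the sum of log2 target levels per cell,
#' smooths it with a running mean over the `span` nearest-proxy cells, takes
#' its central finite-difference gradient with respect to log2 proxy, and
#' retains the cells where the gradient is below `gradient_threshold`
#' (default -0.01 per log2-proxy unit). Cells whose smoothed profile sits
#' mostly within the safety margin of the per-target `T0` or `Tinf`
#' plateaus (more than `max_plateau_fraction` of targets) are additionally
#' dropped: they carry (almost) no responsive target and would feed
#' near-singular entries to the tilde transform. The returned selection is
#' the contiguous proxy interval spanned by the passing cells (after a
#' majority filter that removes isolated noise flips of the gradient test).
#' Cells with proxy below `min_proxy` (no measurable miRNA; gradient 0
#' there) are never selected.
#'
#' @param mat an [expression_matrix()].
#' @param refs a [estimate_reference_levels()] table.
#' @param gradient_threshold slope threshold, `< 0`.
#' @param span smoothing span (cells) for the total-level curve.
#' @param min_proxy lower proxy bound for selectable cells (default 1
#'   molecule).
#' @param max_plateau_fraction drop cells with more than this fraction of
#'   targets inside a margin zone (default 0.9).
#' @return character vector of selected cell ids, ordered by proxy.
#' @export
select_responsive_cells <- function(mat, refs, gradient_threshold = -0.01,
                                    span = 50, min_proxy = 1,
                                    max_plateau_fraction = 0.9) {
  stopifnot(inherits(mat, "ExpressionMatrix"), gradient_threshold < 0)
  mat <- subset_genes(order_by_proxy(mat), refs$target)
  eligible <- mat$proxy >= min_proxy
  if (sum(eligible) < 3) stopf("no responsive region: too few non-zero-proxy cells")
  sub <- subset_cells(mat, which(eligible))
  u <- log2(sub$proxy)
  S <- rowSums(log2(pmax(sub$values, .Machine$double.xmin)))
  win <- nearest_windows(u, min(span, length(u)))
  S_sm <- as.vector(window_means(matrix(S, ncol = 1), win))
  n <- length(S_sm)
  # central differences at a half-span offset: differencing a window-mean
  # curve at adjacent cells is degenerate (neighbouring windows often
  # coincide), so the baseline must be commensurate with the smoothing
  h <- max(1L, floor(min(span, n) / 2))
  im <- pmax(seq_len(n) - h, 1L)
  ip <- pmin(seq_len(n) + h, n)
  g <- (S_sm[ip] - S_sm[im]) / (u[ip] - u[im])
  # Cell-level margin filter: drop cells whose smoothed profile sits mostly
  # inside the margin zones (targets at their T0 or Tinf plateaus) -- such
  # cells contribute near-singular, information-free entries to the tilde
  # transform. Comparison on the linear scale: window means carry the same
  # noise-induced mean inflation as the pool-mean reference levels.
  sm1 <- window_means(sub$values, win)
  plateau <- sweep(sm1, 2, refs$T0 - refs$margin, ">=") |
    sweep(sm1, 2, refs$Tinf + refs$margin, "<=")
  plateau_frac <- rowMeans(plateau)
  pass <- g < gradient_threshold & plateau_frac < max_plateau_fraction
  if (!any(pass)) stopf("no responsive region: no cell passes the gradient filter")
  # Majority-smooth the pass indicator over a span-sized neighbourhood:
  # under noise the gradient test flips cell-by-cell, and the responsive
  # region is where passing cells are dense, not where a literal unbroken
  # run happens to survive
  k <- min(2L * (span %/% 2L) + 1L, 2L * ((n - 1L) %/% 2L) + 1L)
  if (k >= 3) {
    sm_pass <- stats::filter(as.numeric(pass), rep(1 / k, k), sides = 2)
    pass <- ifelse(is.na(sm_pass), pass, sm_pass > 0.5)
  }
  if (!any(pass)) stopf("no responsive region: no cell passes the gradient filter")
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  idx <- starts[best]:ends[best]
  names(sub$proxy)[idx]
}

#' Two-pass smoothing of target levels along the miRNA gradient
#'
#' Pass 1 replaces each entry by the mean over the `first_window` cells with
#' the nearest proxy. Pass 2 repairs entries that fall outside the full
#' admissible range `(Tinf_i, T0_i)` (noise artifacts that would make the
#' tilde transform undefined): it recomputes a running mean of the raw
#' values starting from a window of `second_window_start` nearest cells,
#' iteratively discarding the strongest outlier (largest absolute deviation
#' from the current window mean) until the mean falls inside the range; when
#' a window empties it is doubled locally and the pruning restarts. A target
#' with an entry that cannot be repaired even at the maximal window is
#' dropped (recorded in the `dropped` attribute). Finally, for the stability
#' of the factorization, the interval boundaries are pulled in by the safety
#' margin `c_i`: entries beyond `T0_i - c_i` or `Tinf_i + c_i` are set to
#' that boundary, which bounds the tilde entries away from their
#' singularities while leaving mid-transition values untouched.
#'
#' Two censoring policies handle entries that end up beyond the margin
#' boundaries: `"winsorize"` (default) sets them to the boundary -- the
#' right choice for noisy data, where an out-of-margin window mean reflects
#' measurement error around a plateau; `"drop"` removes the whole target --
#' the right choice for (near-)noise-free data, where such entries are
#' structural (the target genuinely sits at a plateau over part of the
#' selected range, carrying no information about its binding constant).
#'
#' @param mat an [expression_matrix()] restricted to the selected cells
#'   (any order; sorted by proxy internally).
#' @param refs a [estimate_reference_levels()] table.
#' @param first_window pass-1 window size (default 50 cells; 1 disables
#'   smoothing, appropriate when the data carry no measurement noise).
#' @param second_window_start initial pass-2 window size (default 10).
#' @param censored policy for entries beyond the margin boundaries:
#'   `"winsorize"` or `"drop"` (see Details).
#' @return a numeric matrix (cells x targets, rows ordered by proxy) of
#'   smoothed levels, every entry inside its closed margin interval
#'   `[Tinf_i + c_i, T0_i - c_i]`; attributes `dropped` (target ids),
#'   `n_repaired` (pass-2 entry count), `n_clipped` (winsorization count)
#'   and `clipped` (logical mask of winsorized entries).
#' @export
smooth_expression <- function(mat, refs, first_window = 50,
                              second_window_start = 10,
                              censored = c("winsorize", "drop")) {
  censored <- match.arg(censored)
  stopifnot(inherits(mat, "ExpressionMatrix"))
  mat <- subset_genes(order_by_proxy(mat), refs$target)
  x <- mat$values
  n <- nrow(x)
  if (n < 2) stopf("need at least 2 cells to smooth")
  p <- mat$proxy
  win1 <- nearest_windows(p, min(first_window, n))
  sm <- window_means(x, win1)
  dimnames(sm) <- dimnames(x)
  dropped <- character(0)
  n_repaired <- 0L
  for (i in seq_len(ncol(sm))) {
    bad <- which(sm[, i] <= refs$Tinf[i] | sm[, i] >= refs$T0[i])
    ok <- TRUE
    for (j in bad) {
      v <- repair_entry(x[, i], p, j, refs$Tinf[i], refs$T0[i],
                        second_window_start)
      if (is.na(v)) {
        ok <- FALSE
        break
      }
      sm[j, i] <- v
      n_repaired <- n_repaired + 1L
    }
    if (!ok) dropped <- c(dropped, refs$target[i])
  }
  keep <- !(refs$target %in% dropped)
  if (length(dropped) > 0) {
    message(sprintf("smoothing: dropped %d target(s) that could not be brought inside (Tinf, T0)",
                    length(dropped)))
    sm <- sm[, keep, drop = FALSE]
  }
  if (ncol(sm) == 0) stopf("smoothing dropped every target")
  lo <- (refs$Tinf + refs$margin)[keep]
  hi <- (refs$T0 - refs$margin)[keep]
  clipped <- sweep(sm, 2, lo, "<") | sweep(sm, 2, hi, ">")
  if (censored == "drop") {
    bad_targets <- colnames(sm)[colSums(clipped) > 0]
    if (length(bad_targets) > 0) {
      message(sprintf("smoothing: dropped %d structurally insensitive target(s) with out-of-margin entries",
                      length(bad_targets)))
      ok <- !(colnames(sm) %in% bad_targets)
      sm <- sm[, ok, drop = FALSE]
      clipped <- clipped[, ok, drop = FALSE]
      dropped <- c(dropped, bad_targets)
    }
    if (ncol(sm) == 0) stopf("smoothing dropped every target")
  } else {
    sm <- pmin(pmax(sm, matrix(lo, n, ncol(sm), byrow = TRUE)),
               matrix(hi, n, ncol(sm), byrow = TRUE))
  }
  attr(sm, "dropped") <- dropped
  attr(sm, "n_repaired") <- n_repaired
  attr(sm, "n_clipped") <- sum(clipped)
  attr(sm, "clipped") <- clipped
  sm
}

# Repair one out-of-margin entry by pruned running means over growing
# nearest-proxy windows of the raw values. Returns NA when even the maximal
# window cannot produce a mean inside (lo, hi).
repair_entry <- function(raw, p, j, lo, hi, w_start) {
  n <- length(raw)
  w <- min(w_start, n)
  repeat {
    lo_j <- max(1L, j - w + 1L)
    hi_j <- min(j, n - w + 1L)
    cand <- lo_j:hi_j
    span <- p[cand + w - 1L] - p[cand]
    l <- cand[which.min(span)]
    vals <- raw[l:(l + w - 1L)]
    while (length(vals) > 0) {
      mu <- mean(vals)
      if (mu > lo && mu < hi) return(mu)
      vals <- vals[-which.max(abs(vals - mu))]
    }
    if (w >= n) return(NA_real_)
    w <- min(2L * w, n)
  }
}

#' Build the tilde matrix of Michaelis--Menten ratios
#'
#' Inverts the steady-state relation per entry:
#' `tilde_ji = (T0_i/Tinf_i - 1)/(T0_i/T_ji - 1) - 1`, which on exact model
#' data equals `K_M_i / A_F_j`. Requires every `T_ji` strictly inside
#' `(Tinf_i, T0_i)`; the resulting matrix is positive and, in the ideal
#' noise-free case, exactly rank 1.
#'
#' @param T_sm numeric matrix (cells x targets) of smoothed levels, e.g.
#'   from [smooth_expression()].
#' @param refs a [estimate_reference_levels()] table covering the targets
#'   (columns) of `T_sm`.
#' @return a positive matrix of class `TildeMatrix` (cells x targets).
#' @examples
#' refs <- data.frame(target = "t1", T0 = 100, Tinf = 25, margin = 7.5)
#' build_tilde_matrix(matrix(62.5, 1, 1, dimnames = list("c1", "t1")), refs)
#' @export
build_tilde_matrix <- function(T_sm, refs) {
  idx <- match(colnames(T_sm), refs$target)
  if (anyNA(idx)) stopf("targets of 'T_sm' missing from 'refs'")
  T0 <- refs$T0[idx]
  Tinf <- refs$Tinf[idx]
  bad <- which(sweep(T_sm, 2, Tinf, "<=") | sweep(T_sm, 2, T0, ">="),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("entry outside (Tinf, T0): cell '%s', target '%s'",
          rownames(T_sm)[bad[1, 1]], colnames(T_sm)[bad[1, 2]])
  }
  num <- T0 / Tinf - 1
  tilde <- sweep(1 / sweep(1 / T_sm, 2, 1 / T0, "-"), 2, num / T0, "*") - 1
  # equivalent to (T0/Tinf - 1)/(T0/T - 1) - 1, vectorized per column
  class(tilde) <- c("TildeMatrix", class(tilde))
  tilde
}

#' Rank-1 factorization of the tilde matrix
#'
#' Computes the leading singular triplet of `Ttilde` and splits the singular
#' value symmetrically: `x_j = sqrt(s1) U_j1`, `y_i = sqrt(s1) V_i1`, with
#' signs fixed so both vectors are entrywise positive. Then `A_F_j = 1/x_j`
#' and `K_M_i = y_i`, each determined only up to a global factor `a > 0`
#' (`(a x, y/a)` fits equally well); the factor is reported as 1. If the
#' sign-fixed leading vectors still contain non-positive entries the data is
#' structurally not rank-1; the offending cells/targets are reported in a
#' warning and returned (no clipping is applied).
#'
#' @param tilde a positive matrix (cells x targets), e.g. from
#'   [build_tilde_matrix()].
#' @return list with `A_F` (per cell), `K_M` (per target), `x`, `y`,
#'   `residual` (Frobenius-norm fraction of `tilde - x y'`), and
#'   `nonpositive` (list of offending cell/target ids, normally empty).
#' @examples
#' rank_one_decompose(matrix(c(3, 6, 4, 8), 2, 2)) # exact rank 1
#' @export
rank_one_decompose <- function(tilde) {
  if (any(tilde <= 0)) stopf("'tilde' must be entrywise positive")
  sv <- svd(tilde)
  u1 <- sv$u[, 1]
  v1 <- sv$v[, 1]
  if (sum(u1) < 0) {
    u1 <- -u1
    v1 <- -v1
  }
  bad_cells <- which(u1 <= 0)
  bad_targets <- which(v1 <= 0)
  if (length(bad_cells) > 0 || length(bad_targets) > 0) {
    warnf("leading singular vectors have non-positive entries (%d cells, %d targets): data not structurally rank-1",
          length(bad_cells), length(bad_targets))
  }
  s1 <- sv$d[1]
  x <- sqrt(s1) * u1
  y <- sqrt(s1) * v1
  residual <- sqrt(sum(sv$d[-1]^2)) / sqrt(sum(sv$d^2))
  list(
    A_F = stats::setNames(1 / x, rownames(tilde)),
    K_M = stats::setNames(y, colnames(tilde)),
    x = x, y = y, residual = residual,
    nonpositive = list(cells = rownames(tilde)[bad_cells],
                       targets = colnames(tilde)[bad_targets])
  )
}

#' Refine K_M by averaging over cells
#'
#' Given per-cell free-Ago estimates, the identity
#' `tilde_ji = K_M_i / A_F_j` gives `K_M_i` as the mean of
#' `A_F_j * tilde_ji` over cells. Because the cells are sorted and smoothed
#' along the proxy dimension, `A_F` is estimated more precisely than the raw
#' SVD `K_M`, and the averaging transfers that precision to `K_M`. On exact
#' rank-1 data the refined values equal the SVD values.
#'
#' When some entries were winsorized at the margin boundaries (see
#' [smooth_expression()]), those entries are censored observations, not
#' measurements; passing the clip mask via `exclude` drops them from the
#' average (a target with every entry censored falls back to all entries).
#'
#' @param tilde the matrix used in the factorization (cells x targets).
#' @param A_F positive per-cell free-Ago estimates.
#' @param exclude optional logical matrix (same shape as `tilde`) marking
#'   entries to leave out of the average.
#' @return named numeric vector of refined `K_M` per target.
#' @export
refine_km <- function(tilde, A_F, exclude = NULL) {
  if (any(A_F <= 0)) stopf("'A_F' must be positive")
  if (length(A_F) != nrow(tilde)) stopf("'A_F' must have one value per cell")
  prod <- tilde * A_F
  if (is.null(exclude)) {
    return(stats::setNames(colMeans(prod), colnames(tilde)))
  }
  if (!identical(dim(exclude), dim(tilde))) {
    stopf("'exclude' must match the shape of 'tilde'")
  }
  out <- vapply(seq_len(ncol(prod)), function(i) {
    keep <- !exclude[, i]
    if (!any(keep)) keep <- rep(TRUE, nrow(prod))
    mean(prod[keep, i])
  }, numeric(1))
  stats::setNames(out, colnames(tilde))
}

#' Configuration of the inference pipeline
#'
#' @param n_low,n_high reference-pool sizes (see
#'   [estimate_reference_levels()]).
#' @param margin_fraction safety-margin fraction (default 0.10).
#' @param gradient_threshold responsive-cell slope cutoff (default -0.01).
#' @param gradient_span smoothing span of the total-level curve (cells).
#' @param first_window,second_window_start smoothing windows (see
#'   [smooth_expression()]).
#' @param min_proxy lower proxy bound for selectable cells.
#' @param max_plateau_fraction cell-selection plateau-profile cutoff (see
#'   [select_responsive_cells()]).
#' @param censored margin-censoring policy (see [smooth_expression()]);
#'   `"winsorize"` for noisy data, `"drop"` for noise-free data.
#' @param proxy_low,proxy_high optional reference-pool proxy cutoffs
#'   (real-data mode).
#' @return list of class `InferenceConfig`.
#' @export
inference_config <- function(n_low = 1600, n_high = 200,
                             margin_fraction = 0.10,
                             gradient_threshold = -0.01,
                             gradient_span = 50,
                             first_window = 50,
                             second_window_start = 10,
                             min_proxy = 1,
                             max_plateau_fraction = 0.9,
                             censored = c("winsorize", "drop"),
                             proxy_low = NULL, proxy_high = NULL) {
  censored <- match.arg(censored)
  structure(as.list(environment()), class = "InferenceConfig")
}

#' Run the full inference pipeline
#'
#' Chains [estimate_reference_levels()], [select_responsive_cells()],
#' [smooth_expression()], [build_tilde_matrix()], [rank_one_decompose()] and
#' [refine_km()], then computes each retained target's critical free-Ago
#' concentration `A_F^C = K_M * Tinf/T0` from the refined `K_M` and the
#' estimated reference levels. The run is deterministic given the matrix and
#' configuration. All inferred `A_F` and `K_M` values carry an unidentified
#' global scale factor (reported as `scale = 1`); rank orders, pairwise
#' ratios and log-scale correlations are invariant to it. Use
#' [calibrate_scale()] with a known per-cell total-Ago vector to resolve it.
#'
#' @param mat an [expression_matrix()].
#' @param config an [inference_config()].
#' @return an object of class `InferenceResult`: list with `cells`
#'   (data.frame: cell, proxy, A_F), `targets` (data.frame: target, T0,
#'   Tinf, K_M_svd, K_M, A_F_C), `residual`, `scale`, `dropped`, `config`.
#' @export
run_inference <- function(mat, config = inference_config()) {
  stopifnot(inherits(mat, "ExpressionMatrix"), inherits(config, "InferenceConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("[%s] %s", name, conditionMessage(e))
    })
  }
  refs <- stage("reference-levels", estimate_reference_levels(
    mat, n_low = config$n_low, n_high = config$n_high,
    margin_fraction = config$margin_fraction,
    proxy_low = config$proxy_low, proxy_high = config$proxy_high
  ))
  sel <- stage("cell-selection", select_responsive_cells(
    mat, refs, gradient_threshold = config$gradient_threshold,
    span = config$gradient_span, min_proxy = config$min_proxy,
    max_plateau_fraction = config$max_plateau_fraction
  ))
  sub <- subset_cells(mat, sel)
  sm <- stage("smoothing", smooth_expression(
    sub, refs, first_window = config$first_window,
    second_window_start = config$second_window_start,
    censored = config$censored
  ))
  refs_kept <- refs[match(colnames(sm), refs$target), , drop = FALSE]
  tilde <- stage("tilde-matrix", build_tilde_matrix(sm, refs_kept))
  dec <- stage("svd", rank_one_decompose(tilde))
  K_M <- stage("refinement", refine_km(tilde, dec$A_F,
                                       exclude = attr(sm, "clipped")))
  A_F_C <- critical_free_ago(K_M, refs_kept$T0, refs_kept$Tinf)
  res <- list(
    cells = data.frame(cell = rownames(tilde),
                       proxy = mat$proxy[rownames(tilde)],
                       A_F = unname(dec$A_F),
                       stringsAsFactors = FALSE, row.names = NULL),
    targets = data.frame(target = colnames(tilde),
                         T0 = refs_kept$T0, Tinf = refs_kept$Tinf,
                         K_M_svd = unname(dec$K_M), K_M = unname(K_M),
                         A_F_C = unname(A_F_C),
                         stringsAsFactors = FALSE, row.names = NULL),
    residual = dec$residual,
    scale = 1,
    scale_identified = FALSE,
    dropped = list(reference = attr(refs, "dropped"),
                   smoothing = attr(sm, "dropped")),
    n_repaired = attr(sm, "n_repaired"),
    n_clipped = attr(sm, "n_clipped"),
    config = config
  )
  class(res) <- "InferenceResult"
  res
}

#' @export
print.InferenceResult <- function(x, ...) {
  cat(sprintf("<InferenceResult> %d cells, %d targets; rank-1 residual %.3g; scale %s\n",
              nrow(x$cells), nrow(x$targets), x$residual,
              if (x$scale_identified) format(x$scale) else "unidentified (1)"))
  invisible(x)
}

#' Resolve the global scale factor from known total-Ago levels
#'
#' The factorization determines `(A_F, K_M)` only up to `(a A_F, a K_M)`.
#' When the per-cell total Ago-miRNA `A_total` is known (synthetic truth, or
#' an absolute calibration), the factor can be fixed by requiring that the
#' implied totals `a A_F_j + sum_i f_i(a A_F_j) T_i*` match `A_total_j` in
#' the least-squares sense on the log scale.
#'
#' @param result an [run_inference()] result.
#' @param A_total named numeric vector of true totals (names = cell ids;
#'   must cover the retained cells).
#' @return the result with `A_F`, `K_M`, `A_F_C` rescaled and
#'   `scale_identified = TRUE`.
#' @export
calibrate_scale <- function(result, A_total) {
  stopifnot(inherits(result, "InferenceResult"))
  at <- A_total[result$cells$cell]
  if (anyNA(at)) stopf("'A_total' must cover all retained cells")
  tg <- result$targets
  implied_total <- function(a) {
    vapply(a * result$cells$A_F, function(af) {
      f <- af / (af + a * tg$K_M)
      af + sum(f * tg$T0 / (1 + f * (tg$T0 / tg$Tinf - 1)))
    }, numeric(1))
  }
  obj <- function(loga) sum((log(implied_total(exp(loga))) - log(at))^2)
  a <- exp(stats::optimize(obj, c(-30, 30))$minimum)
  result$cells$A_F <- a * result$cells$A_F
  result$targets$K_M <- a * result$targets$K_M
  result$targets$K_M_svd <- a * result$targets$K_M_svd
  result$targets$A_F_C <- a * result$targets$A_F_C
  result$scale <- a
  result$scale_identified <- TRUE
  result
}
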