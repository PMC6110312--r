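# Sliding-window single-cell statistics along the miRNA-proxy axis:
# coefficient-of-variation and pairwise-correlation curves normalized to a
# non-target background, target-panel selection and fold-change-by-rank
# curves.

new_stat_curve <- function(df, window, background) {
  structure(df, class = c("SlidingStatCurve", "data.frame"),
            window = window, background = background)
}

# Window indices (reference cell + window-1 nearest by proxy) for a matrix
# already sorted by proxy.
stat_windows <- function(p, window) {
  if (window > length(p)) stopf("'window' must be <= cell count")
  nearest_windows(p, window)
}

#' Sliding-window coefficient of variation of targets vs background
#'
#' Traverses the cells in proxy order; for each reference cell, takes the
#' window of `window` cells nearest in proxy (the reference plus
#' `window - 1` neighbours), computes each gene's coefficient of variation
#' (SD/mean) across the window, log2-transforms, and averages separately
#' over the target set and the background set. The curve reports the
#' difference of the two log2 means (i.e. log2 of the CV ratio) with the
#' standard error over targets. Genes with non-positive mean in a window are
#' skipped for that window.
#'
#' @param mat an [expression_matrix()].
#' @param targets,background disjoint character vectors of gene ids.
#' @param window window size in cells (default 200: reference + 199
#'   nearest).
#' @return a `SlidingStatCurve` data.frame: `cell`, `proxy`, `value`
#'   (log2 CV ratio), `se`.
#' @export
sliding_cv <- function(mat, targets, background, window = 200) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (length(intersect(targets, background)) > 0 &&
      !identical(sort(targets), sort(background))) {
    stopf("'targets' and 'background' must be disjoint")
  }
  mat <- order_by_proxy(mat)
  genes <- union(targets, background)
  x <- mat$values[, genes, drop = FALSE]
  win <- stat_windows(mat$proxy, window)
  cs <- apply(x, 2, cumsum)
  cs2 <- apply(x^2, 2, cumsum)
  cs <- rbind(0, cs)
  cs2 <- rbind(0, cs2)
  w <- window
  it <- match(targets, genes)
  ib <- match(background, genes)
  n <- nrow(x)
  value <- se <- numeric(n)
  for (j in seq_len(n)) {
    l <- win[j, "l"]
    r <- win[j, "r"]
    mu <- (cs[r + 1L, ] - cs[l, ]) / w
    vv <- pmax((cs2[r + 1L, ] - cs2[l, ]) / w - mu^2, 0) * w / (w - 1)
    cv <- ifelse(mu > 0, sqrt(vv) / mu, NA_real_)
    lt <- log2(cv[it])
    lb <- log2(cv[ib])
    lt <- lt[is.finite(lt)]
    lb <- lb[is.finite(lb)]
    value[j] <- mean(lt) - mean(lb)
    se[j] <- stats::sd(lt) / sqrt(length(lt))
  }
  new_stat_curve(
    data.frame(cell = rownames(x), proxy = unname(mat$proxy),
               value = value, se = se,
               stringsAsFactors = FALSE, row.names = NULL),
    window = window, background = sprintf("%d genes", length(background))
  )
}

#' Sliding-window mean pairwise correlation of targets vs background
#'
#' For each reference cell's window, computes the mean Pearson correlation
#' of log2 expression over all pairs of target genes, and divides it by the
#' mean over `n_background_draws` random same-size sets of background
#' genes (the background sets are drawn once, under `seed`, and reused for
#' every window). Zero-variance genes in a window are skipped pair-wise.
#'
#' @inheritParams sliding_cv
#' @param background_pool character vector of candidate background genes.
#' @param n_background_draws number of random background sets (default 50).
#' @param seed seed for the background draws.
#' @param step evaluate every `step`-th reference cell (default 1 = all).
#' @return a `SlidingStatCurve` data.frame: `cell`, `proxy`, `value` (ratio
#'   of mean pairwise correlations), `target_r`, `background_r`, `se` (SE
#'   over target pairs).
#' @export
sliding_pairwise_correlation <- function(mat, targets, background_pool,
                                         window = 200,
                                         n_background_draws = 50,
                                         seed = 1, step = 1) {
  stopifnot(inherits(mat, "ExpressionMatrix"), n_background_draws >= 1)
  if (length(intersect(targets, background_pool)) > 0) {
    stopf("'targets' and 'background_pool' must be disjoint")
  }
  mat <- order_by_proxy(mat)
  p <- length(targets)
  sets <- with_seed(seed, {
    lapply(seq_len(n_background_draws), function(k) {
      sample(background_pool, min(p, length(background_pool)))
    })
  })
  win <- stat_windows(mat$proxy, window)
  lx <- log2(pmax(mat$values, .Machine$double.xmin))
  refs_idx <- seq(1, nrow(lx), by = step)
  mean_pair_r <- function(sub) {
    cm <- suppressWarnings(stats::cor(sub))
    vals <- cm[upper.tri(cm)]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) return(c(NA_real_, NA_real_))
    c(mean(vals), stats::sd(vals) / sqrt(length(vals)))
  }
  out <- lapply(refs_idx, function(j) {
    rows <- win[j, "l"]:win[j, "r"]
    tr <- mean_pair_r(lx[rows, targets, drop = FALSE])
    br <- mean(vapply(sets, function(s) {
      mean_pair_r(lx[rows, s, drop = FALSE])[1]
    }, numeric(1)), na.rm = TRUE)
    c(tr[1], br, tr[2])
  })
  out <- do.call(rbind, out)
  new_stat_curve(
    data.frame(cell = rownames(lx)[refs_idx],
               proxy = unname(mat$proxy[refs_idx]),
               value = out[, 1] / out[, 2],
               target_r = out[, 1], background_r = out[, 2], se = out[, 3],
               stringsAsFactors = FALSE, row.names = NULL),
    window = window,
    background = sprintf("%d draws of %d genes", n_background_draws, p)
  )
}

#' Select the analysis target panel from prediction scores
#'
#' Ranks genes by prediction score (descending), keeps those expressed
#' above `min_expression` in the miRNA-free state and down-regulated by at
#' least the required amount under saturating miRNA
#' (`log2(Tinf/T0) < max_log2_ratio`; the default -0.12 corresponds to at
#' least 8% down-regulation since `2^-0.12 ~ 0.92`), and returns the top
#' `top_n` of the survivors.
#'
#' @param scores data.frame with columns `target` (gene id) and `score`.
#' @param refs a [estimate_reference_levels()] table (columns `target`,
#'   `T0`, `Tinf`).
#' @param top_n panel size (default 300).
#' @param min_expression minimum `T0` (default 8).
#' @param max_log2_ratio down-regulation cutoff on `log2(Tinf/T0)`
#'   (default -0.12).
#' @return data.frame of the selected panel, ranked by score.
#' @export
select_targets <- function(scores, refs, top_n = 300, min_expression = 8,
                           max_log2_ratio = -0.12) {
  stopifnot(all(c("target", "score") %in% names(scores)))
  m <- merge(scores, refs[, c("target", "T0", "Tinf")], by = "target")
  m$log2_ratio <- log2(m$Tinf / m$T0)
  keep <- m$T0 >= min_expression & m$log2_ratio < max_log2_ratio
  if (!any(keep)) stopf("empty panel: no gene passes both filters")
  m <- m[keep, , drop = FALSE]
  m <- m[order(-m$score, m$target), , drop = FALSE]
  utils::head(m, top_n)
}

#' Cumulative mean fold change over top-ranked targets
#'
#' Sorts targets by a ranking key and returns the running mean of the log2
#' fold change over the top `x` targets for `x = 1..n` -- the curve used to
#' ask which inferred parameter best predicts down-regulation.
#'
#' @param log2_fc named numeric vector of per-target log2 fold changes
#'   (`log2(Tinf/T0)`; negative = down-regulated).
#' @param key numeric ranking key aligned with `log2_fc`.
#' @param direction `"desc"` to rank by decreasing key (scores, K_M) or
#'   `"asc"` for increasing key (A_F^C).
#' @return data.frame with columns `n_top`, `target`, `mean_log2_fc`.
#' @export
fold_change_by_rank <- function(log2_fc, key,
                                direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  if (length(log2_fc) != length(key)) stopf("'log2_fc' and 'key' must align")
  o <- order(key, decreasing = (direction == "desc"))
  fc <- log2_fc[o]
  data.frame(
    n_top = seq_along(fc),
    target = if (is.null(names(fc))) NA_character_ else names(fc),
    mean_log2_fc = cumsum(fc) / seq_along(fc),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
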