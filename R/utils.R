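# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Deterministic sub-seed derivation from a master seed
#'
#' Linear-congruential mix keeping results in the 32-bit signed range so the
#' value is always a valid `set.seed()` argument.
#' @noRd
derive_seed <- function(master, offset) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 48271 + 12345 * (offset + 1)) %% m)
}

#' Nearest-neighbour window indices on a sorted numeric vector
#'
#' For each position `j` of the sorted vector `p`, returns the contiguous
#' window of `size` elements containing `j` whose span `p[r] - p[l]` is
#' minimal, i.e. the `size` values nearest to `p[j]`. Ties resolve to the
#' leftmost window (stable for equal proxies).
#'
#' @return integer matrix with columns `l`, `r` (1-based inclusive bounds)
#' @noRd
nearest_windows <- function(p, size) {
  n <- length(p)
  size <- min(size, n)
  l <- integer(n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - size + 1L)
    hi <- min(j, n - size + 1L)
    cand <- lo:hi
    span <- p[cand + size - 1L] - p[cand]
    l[j] <- cand[which.min(span)]
  }
  cbind(l = l, r = l + size - 1L)
}

#' Running window means per column via cumulative sums
#' @param x numeric matrix (rows ordered as `win` indices refer to)
#' @param win window matrix from [nearest_windows()]
#' @noRd
window_means <- function(x, win) {
  cs <- apply(x, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(x))
  cs0 <- rbind(0, cs)
  (cs0[win[, "r"] + 1L, , drop = FALSE] - cs0[win[, "l"], , drop = FALSE]) /
    (win[, "r"] - win[, "l"] + 1L)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
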