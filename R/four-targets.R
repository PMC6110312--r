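#' A four-target showcase network
#'
#' A small panel used to illustrate the single-cell behaviour of competing
#' miRNA targets: expression levels span a wide range, two targets (`a`,
#' `b`) bind the miRNA with high affinity (low `K_M`, repressed already at
#' low miRNA levels) and two (`c`, `d`) with low affinity (high `K_M`,
#' responding only at high miRNA levels); down-regulation is moderate
#' (three- to four-fold) for all four.
#'
#' @return a [target_params()] table with targets `a`, `b`, `c`, `d`.
#' @examples
#' p <- four_target_params()
#' p$K_M
#' @export
four_target_params <- function() {
  target_params(
    alpha = c(50, 5, 20, 2),
    delta = c(0.1, 0.1, 0.1, 0.1),
    k_on = c(1, 1, 0.05, 0.05),
    k_off = c(0.1, 0.1, 0.5, 0.5),
    k_cat = c(0.3, 0.4, 0.3, 0.4),
    id = c("a", "b", "c", "d")
  )
}

#' Log-spaced grid of per-cell miRNA levels
#'
#' Virtual cells with total Ago-miRNA levels placed uniformly in log2 space
#' -- the layout used to trace dose-response curves of the
#' [four_target_params()] system across its sensitive range.
#'
#' @param n number of cells (default 50).
#' @param log2_range length-2 range of `log2(A_total)` (default `c(0, 12)`,
#'   spanning both the high- and low-affinity transitions of the
#'   four-target system).
#' @return numeric vector of `A_total` values.
#' @export
mirna_grid <- function(n = 50, log2_range = c(0, 12)) {
  2^seq(log2_range[1], log2_range[2], length.out = n)
}
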