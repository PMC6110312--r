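# Deterministic ceRNA titration: induce one designated competing RNA over a
# range of transcription rates and quantify the steady-state de-repression
# of the low- and high-K_M target pools.

#' Define a ceRNA titration scenario
#'
#' A scenario consists of a background panel of miRNA targets, one
#' designated competing RNA (the ceRNA) whose transcription rate is swept
#' over a set of induction levels, a fixed total Ago-miRNA level, and the
#' `K_M` cutoffs defining the low- and high-affinity pools that are read
#' out. Default ceRNA constants: free-decay 0.1/h and binding rate 0.2, with
#' the bound ceRNA either stabilized (`k_cat = 0.002`/h, giving
#' `K_M = 0.01`, a strong sponge) or destabilized (`k_cat = 0.2`/h,
#' `K_M = 1`).
#'
#' @param background a [target_params()] table (the resident target panel).
#' @param cerna_kind `"stabilized"` (long-lived in the complex) or
#'   `"destabilized"`; ignored when `cerna` is given.
#' @param cerna optional single-row [target_params()] overriding the ceRNA
#'   constants (its `alpha` is replaced by the induction levels).
#' @param induction_levels increasing non-negative ceRNA transcription
#'   rates; default three levels spanning the background panel's total
#'   transcription (0.3x, 1x, 3x of `sum(alpha)`).
#' @param A_total total Ago-miRNA level; default half the background's
#'   saturating binding capacity `sum(Tinf)`.
#' @param low_cutoff,high_cutoff `K_M` pool boundaries (defaults 0.02
#'   and 2).
#' @return list of class `CernaScenario`.
#' @export
cerna_scenario <- function(background,
                           cerna_kind = c("stabilized", "destabilized"),
                           cerna = NULL,
                           induction_levels = NULL,
                           A_total = NULL,
                           low_cutoff = 0.02, high_cutoff = 2) {
  validate_target_params(background)
  if (low_cutoff >= high_cutoff) stopf("'low_cutoff' must be < 'high_cutoff'")
  if (is.null(cerna)) {
    cerna_kind <- match.arg(cerna_kind)
    k_cat <- if (cerna_kind == "stabilized") 0.002 else 0.2
    cerna <- target_params(alpha = 1, delta = 0.1, k_on = 0.2, k_off = 0,
                           k_cat = k_cat, id = "ceRNA")
  }
  if (nrow(cerna) != 1) stopf("'cerna' must describe a single transcript")
  if (is.null(induction_levels)) {
    induction_levels <- sum(background$alpha) * c(0.3, 1, 3)
  }
  if (any(induction_levels < 0) || is.unsorted(induction_levels)) {
    stopf("'induction_levels' must be non-negative and increasing")
  }
  if (is.null(A_total)) A_total <- 0.5 * sum(background$Tinf)
  low <- background$K_M < low_cutoff
  high <- background$K_M > high_cutoff
  if (!any(low) || !any(high)) {
    stopf("background pools non-empty required: %d low-K_M, %d high-K_M targets",
          sum(low), sum(high))
  }
  structure(
    list(background = background, cerna = cerna,
         induction_levels = induction_levels, A_total = A_total,
         low_cutoff = low_cutoff, high_cutoff = high_cutoff),
    class = "CernaScenario"
  )
}

#' Draw a default ceRNA background panel
#'
#' The benchmark's rate laws with the binding-rate spreads widened (log2-sd
#' 3 for `k_on` and `k_off`) so that the `K_M` distribution spans both pool
#' cutoffs; panels are redrawn (bounded retries) until both pools are
#' populated.
#'
#' @param M panel size (default 300).
#' @param seed integer seed.
#' @param low_cutoff,high_cutoff pool boundaries the panel must populate.
#' @return a [target_params()] table.
#' @export
cerna_background <- function(M = 300, seed = 1,
                             low_cutoff = 0.02, high_cutoff = 2) {
  for (try in 1:50) {
    spec <- benchmark_spec(
      M = M, N = 10,
      rate_log2_sd = c(alpha = 1, delta = 1, k_on = 3, k_off = 3, k_cat = 1),
      seed = derive_seed(seed, try)
    )
    bg <- draw_target_params(spec)
    if (any(bg$K_M < low_cutoff) && any(bg$K_M > high_cutoff)) return(bg)
  }
  stopf("could not draw a background populating both K_M pools")
}

#' Steady-state pool response to ceRNA induction
#'
#' For each induction level, solves the full competitive steady state with
#' the ceRNA included in the network, sums the total target levels within
#' the low- and high-`K_M` pools, and reports the fractional change of each
#' pool relative to the zero-induction baseline. Inducing a competitor can
#' only sequester miRNA, so pool changes are non-negative and monotone
#' non-decreasing in the induction level; with `A_total = 0` they are
#' identically zero.
#'
#' @param scenario a [cerna_scenario()].
#' @return data.frame with columns `induction` (ceRNA `alpha`), `pool`
#'   (`"low_KM"` / `"high_KM"`), `total`, `fractional_change`, plus
#'   `A_free`.
#' @export
cerna_response <- function(scenario) {
  stopifnot(inherits(scenario, "CernaScenario"))
  bg <- scenario$background
  low <- bg$K_M < scenario$low_cutoff
  high <- bg$K_M > scenario$high_cutoff
  pool_totals <- function(alpha_cerna) {
    if (alpha_cerna == 0) {
      st <- solve_free_ago(bg, scenario$A_total)
      tot <- st$m + st$Am
      list(low = sum(tot[low]), high = sum(tot[high]), A_free = st$A_free)
    } else {
      ce <- scenario$cerna
      full <- target_params(
        alpha = c(bg$alpha, alpha_cerna),
        delta = c(bg$delta, ce$delta),
        k_on = c(bg$k_on, ce$k_on),
        k_off = c(bg$k_off, ce$k_off),
        k_cat = c(bg$k_cat, ce$k_cat),
        id = c(bg$id, ce$id)
      )
      st <- solve_free_ago(full, scenario$A_total)
      tot <- (st$m + st$Am)[seq_len(nrow(bg))]
      list(low = sum(tot[low]), high = sum(tot[high]), A_free = st$A_free)
    }
  }
  base <- pool_totals(0)
  levels <- scenario$induction_levels
  rows <- lapply(levels, function(a) {
    pt <- pool_totals(a)
    data.frame(
      induction = a,
      pool = c("low_KM", "high_KM"),
      total = c(pt$low, pt$high),
      fractional_change = c((pt$low - base$low) / base$low,
                            (pt$high - base$high) / base$high),
      A_free = pt$A_free,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
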