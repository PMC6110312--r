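#' Per-target kinetic parameters
#'
#' Builds a validated table of kinetic rate constants for a panel of miRNA
#' targets. Each target is described by its transcription rate `alpha`
#' (molecules/h), free-mRNA decay rate `delta` (/h), Ago--miRNA binding rate
#' `k_on` (per molecule per h, with unit cell volume so that abundances and
#' concentrations coincide), dissociation rate `k_off` (/h) and the decay
#' rate of the miRNA-bound mRNA `k_cat` (/h).
#'
#' Three derived constants are attached:
#' * `T0 = alpha/delta`, the steady-state total level with no miRNA;
#' * `Tinf = alpha/k_cat`, the level under saturating miRNA;
#' * `K_M = (k_off + k_cat)/k_on`, the Michaelis--Menten constant.
#'
#' Down-regulation by the miRNA requires `k_cat > delta`, i.e. `Tinf < T0`;
#' targets violating this are accepted by the model operations but rejected
#' where the analysis assumes repression (see [critical_free_ago()]).
#'
#' @param alpha,delta,k_on,k_off,k_cat numeric vectors of equal length (or
#'   length 1, recycled); all `> 0` except `k_off >= 0`.
#' @param id optional character vector of target labels; defaults to
#'   `"t1", "t2", ...`.
#' @return a `data.frame` of class `TargetParams` with columns `id`, the five
#'   rates, and derived `T0`, `Tinf`, `K_M`.
#' @examples
#' target_params(alpha = 10, delta = 0.1, k_on = 0.2, k_off = 0.1, k_cat = 0.4)
#' @export
target_params <- function(alpha, delta, k_on, k_off, k_cat, id = NULL) {
  n <- max(length(alpha), length(delta), length(k_on), length(k_off),
           length(k_cat))
  p <- data.frame(
    id = if (is.null(id)) paste0("t", seq_len(n)) else as.character(id),
    alpha = rep_len(as.numeric(alpha), n),
    delta = rep_len(as.numeric(delta), n),
    k_on = rep_len(as.numeric(k_on), n),
    k_off = rep_len(as.numeric(k_off), n),
    k_cat = rep_len(as.numeric(k_cat), n),
    stringsAsFactors = FALSE
  )
  validate_target_params(p)
  p$T0 <- p$alpha / p$delta
  p$Tinf <- p$alpha / p$k_cat
  p$K_M <- km_constant(p$k_off, p$k_cat, p$k_on)
  class(p) <- c("TargetParams", "data.frame")
  p
}

validate_target_params <- function(p) {
  if (anyDuplicated(p$id)) stopf("duplicated target ids")
  for (col in c("alpha", "delta", "k_on", "k_cat")) {
    if (any(!is.finite(p[[col]]) | p[[col]] <= 0)) {
      stopf("'%s' must be finite and > 0", col)
    }
  }
  if (any(!is.finite(p$k_off) | p$k_off < 0)) {
    stopf("'k_off' must be finite and >= 0")
  }
  invisible(p)
}

#' Read / write target parameter tables
#'
#' TSV with header columns `id`, `alpha`, `delta`, `k_on`, `k_off`, `k_cat`;
#' derived columns are recomputed on read.
#'
#' @param path file path.
#' @param params a [target_params()] table.
#' @return `read_target_params()` returns a `TargetParams` table;
#'   `write_target_params()` returns `path` invisibly.
#' @export
read_target_params <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "alpha", "delta", "k_on", "k_off", "k_cat")
  if (!all(need %in% names(x))) {
    stopf("parameter TSV must have columns: %s", paste(need, collapse = ", "))
  }
  target_params(x$alpha, x$delta, x$k_on, x$k_off, x$k_cat, id = x$id)
}

#' @rdname read_target_params
#' @export
write_target_params <- function(params, path) {
  utils::write.table(
    params[, c("id", "alpha", "delta", "k_on", "k_off", "k_cat")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
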