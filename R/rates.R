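#' Division-error rate set for the heart-lineage simulator
#'
#' Bundles the per-division error probabilities that perturb the stereotyped
#' wild-type lineage in simulated hemisegments. Three categories of error are
#' modeled, mirroring the three categories of cardiac progenitor cell division:
#' the earlier-stage division that normally yields exactly two Svp progenitors,
#' the asymmetric division of each Svp progenitor into one Svp cardial cell
#' (Svp-CC) and one Svp pericardial cell (Svp-PC), and the symmetric division
#' of each Tin progenitor into two Tin cardial cells (Tin-CCs).
#'
#' @param r_early Probability that the earlier-stage division produces 1 or 3
#'   Svp progenitors instead of 2 (the two miscounts are equally likely).
#' @param r_asym Probability that a given Svp progenitor's asymmetric division
#'   fails; the failure mode is then drawn from `asym_mode_weights`.
#' @param asym_mode_weights Length-3 probability vector over the asymmetric
#'   failure modes: `both_cc` (two Svp-CCs, no PC), `both_pc` (two Svp-PCs, no
#'   CC), and `karyokinesis` (a single undivided, enlarged-nucleus Svp-CC with
#'   its PC missing).
#' @param r_sym Probability that a given Tin progenitor's symmetric division
#'   fails; the failure mode is then drawn from `sym_mode_weights`.
#' @param sym_mode_weights Length-2 probability vector over the symmetric
#'   failure modes: `one` (no division, 1 Tin-CC) and `three` (an extra
#'   division, 3 Tin-CCs).
#' @param r_dropout Probability that a hemisegment is unscoreable (e.g. damaged
#'   or obscured in the preparation) and excluded from all denominators.
#'
#' @return An object of class `division_error_rates` (a named list).
#' @examples
#' division_error_rates()                    # error-free wild type
#' division_error_rates(r_asym = 0.25)      # frequent asymmetric failures
#' @export
division_error_rates <- function(r_early = 0,
                                 r_asym = 0,
                                 asym_mode_weights = c(both_cc = 1/3,
                                                       both_pc = 1/3,
                                                       karyokinesis = 1/3),
                                 r_sym = 0,
                                 sym_mode_weights = c(one = 0.5, three = 0.5),
                                 r_dropout = 0) {
  rates <- list(
    r_early = r_early,
    r_asym = r_asym,
    asym_mode_weights = as.numeric(asym_mode_weights),
    r_sym = r_sym,
    sym_mode_weights = as.numeric(sym_mode_weights),
    r_dropout = r_dropout
  )
  class(rates) <- "division_error_rates"
  validate_rates(rates)
  names(rates$asym_mode_weights) <- c("both_cc", "both_pc", "karyokinesis")
  names(rates$sym_mode_weights) <- c("one", "three")
  rates
}

validate_rates <- function(rates) {
  if (!inherits(rates, "division_error_rates")) {
    stop("`rates` must be created with division_error_rates()", call. = FALSE)
  }
  probs <- c(rates$r_early, rates$r_asym, rates$r_sym, rates$r_dropout,
             rates$asym_mode_weights, rates$sym_mode_weights)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("all rates and mode weights must lie in [0, 1]", call. = FALSE)
  }
  if (length(rates$asym_mode_weights) != 3 ||
      abs(sum(rates$asym_mode_weights) - 1) > 1e-8) {
    stop("`asym_mode_weights` must be a 3-vector summing to 1", call. = FALSE)
  }
  if (length(rates$sym_mode_weights) != 2 ||
      abs(sum(rates$sym_mode_weights) - 1) > 1e-8) {
    stop("`sym_mode_weights` must be a 2-vector summing to 1", call. = FALSE)
  }
  invisible(rates)
}

#' @export
print.division_error_rates <- function(x, ...) {
  cat("Division error rates:\n")
  cat(sprintf("  earlier-stage miscount (r_early): %g\n", x$r_early))
  cat(sprintf("  asymmetric failure     (r_asym) : %g  [both-CC %g, both-PC %g, karyokinesis %g]\n",
              x$r_asym, x$asym_mode_weights[1], x$asym_mode_weights[2],
              x$asym_mode_weights[3]))
  cat(sprintf("  symmetric failure      (r_sym)  : %g  [1 cell %g, 3 cells %g]\n",
              x$r_sym, x$sym_mode_weights[1], x$sym_mode_weights[2]))
  cat(sprintf("  hemisegment dropout    (r_drop) : %g\n", x$r_dropout))
  invisible(x)
}
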