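# Permutation inference on per-embryo defect proportions: least-squares fits
# of genotype models and label-permutation p-values, including a
# Smith-orthogonalization permutation test of the interaction (synergy)
# coefficient in the two-mutation model.

new_permutation_result <- function(statistic, n, n_perm, p, alternative,
                                   seed = NULL, mode = "sampled") {
  structure(
    list(statistic = statistic, n = n, n_perm = n_perm, p = p,
         alternative = alternative, seed = seed, mode = mode),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, alternative = '%s')\n", x$mode,
              x$alternative))
  cat(sprintf("  statistic = %.6g\n", x$statistic))
  if (x$mode == "exhaustive") {
    cat(sprintf("  exceedances (incl. observed) = %d of %d assignments\n",
                x$n, x$n_perm))
    cat(sprintf("  p = %.6g\n", x$p))
  } else {
    cat(sprintf("  exceedances n = %d of N = %d permutations\n", x$n, x$n_perm))
    cat(sprintf("  p = (n + 1) / (N + 1) = %.6g\n", x$p))
  }
  invisible(x)
}

check_two_groups <- function(y, group) {
  if (length(y) != length(group)) stop("`y` and `group` lengths differ")
  if (anyNA(y) || anyNA(group)) stop("missing values in response or labels")
  if (!all(group %in% c(0, 1))) stop("`group` must be a 0/1 indicator")
  if (sum(group == 1) == 0 || sum(group == 0) == 0) {
    stop("both groups must be non-empty")
  }
  invisible(NULL)
}

#' Fit the two-group general linear model
#'
#' Ordinary least squares of `Yj = b0 + b1*Ij + ej`, where `Ij` indicates the
#' mutant group. In closed form, `b0` is the reference-group mean and `b1` the
#' difference of group means (mutant minus reference); `b1` is the tested
#' statistic.
#'
#' @param y Numeric response (per-embryo defect proportions).
#' @param group 0/1 indicator (1 = mutant/phenotype of interest).
#' @return A list with `coefficients` (`b0`, `b1`), `residuals`, and
#'   `statistic` (= `b1`).
#' @examples
#' fit_two_group(c(0.1, 0.2, 0.4, 0.5), c(0, 0, 1, 1))$statistic  # 0.3
#' @export
fit_two_group <- function(y, group) {
  check_two_groups(y, group)
  b0 <- mean(y[group == 0])
  b1 <- mean(y[group == 1]) - b0
  fitted <- b0 + b1 * group
  list(coefficients = c(b0 = b0, b1 = b1), residuals = y - fitted,
       statistic = b1)
}

# Exceedance count under the ">= observed" rule (ties count), by alternative.
count_exceedances <- function(stats, observed, alternative) {
  switch(alternative,
    greater = sum(stats >= observed),
    less = sum(stats <= observed),
    two.sided = sum(abs(stats) >= abs(observed)),
    stop("unknown alternative: ", alternative)
  )
}

#' Permutation test of the two-group coefficient
#'
#' Shuffles the genotype labels among embryos `n_perm` times (group sizes
#' preserved), recomputes the group-difference coefficient `b1` for each
#' shuffle, and counts the permutation estimates that equal or exceed the
#' observed estimate (under `alternative = "greater"`, the default; `"less"`
#' and `"two.sided"` use the mirrored and absolute-value rules). The p-value
#' is `(n + 1) / (N + 1)`, which is floored at `1 / (N + 1)` and can never
#' reach 0.
#'
#' @inheritParams fit_two_group
#' @param n_perm Number of permutations `N` (default `1e6`, suitable for
#'   highly reproducible p-values; use fewer for exploratory runs).
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @param seed Optional integer seed for the label shuffles.
#' @return A `permutation_result` object.
#' @examples
#' y <- c(0, 0.05, 0.1, 0.4, 0.45, 0.5)
#' permutation_test_two_group(y, c(0, 0, 0, 1, 1, 1), n_perm = 999, seed = 1)
#' @export
permutation_test_two_group <- function(y, group, n_perm = 1e6,
                                       alternative = c("greater", "less",
                                                       "two.sided"),
                                       seed = NULL) {
  alternative <- match.arg(alternative)
  check_two_groups(y, group)
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  n_perm <- as.integer(n_perm)
  if (!is.null(seed)) set.seed(seed)
  if (stats::var(y) == 0 && alternative == "two.sided") {
    message("constant response: degenerate permutation distribution, p = 1")
  }

  n_total <- length(y)
  n1 <- sum(group == 1)
  total <- sum(y)
  mean_from_sum1 <- function(s1) s1 / n1 - (total - s1) / (n_total - n1)
  # same arithmetic path as the permuted statistics, so ties are exact
  observed <- mean_from_sum1(sum(y[group == 1]))

  n_exceed <- 0L
  chunk <- 100000L
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    idx <- vapply(seq_len(b), function(i) sample.int(n_total, n1),
                  integer(n1))
    s1 <- colSums(matrix(y[idx], nrow = n1))
    n_exceed <- n_exceed + count_exceedances(mean_from_sum1(s1), observed,
                                             alternative)
    done <- done + b
  }
  new_permutation_result(observed, n_exceed, n_perm,
                         (n_exceed + 1) / (n_perm + 1), alternative, seed)
}

#' Exact two-group permutation test by full enumeration
#'
#' Enumerates every assignment of the group labels that preserves the group
#' sizes (all `choose(n, n1)` of them) and reports the exact permutation
#' p-value: the fraction of assignments, including the observed one, whose
#' coefficient equals or exceeds the observed coefficient. Serves as the
#' oracle for the sampled test on small designs.
#'
#' @inheritParams permutation_test_two_group
#' @param max_n Enumeration guard on the total number of embryos (default 20).
#' @return A `permutation_result` with `mode = "exhaustive"`.
#' @examples
#' exhaustive_two_group(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))$p  # 1/20
#' @export
exhaustive_two_group <- function(y, group,
                                 alternative = c("greater", "less",
                                                 "two.sided"),
                                 max_n = 20) {
  alternative <- match.arg(alternative)
  check_two_groups(y, group)
  n_total <- length(y)
  if (n_total > max_n) {
    stop("enumeration bound exceeded: ", n_total, " > ", max_n)
  }
  n1 <- sum(group == 1)
  total <- sum(y)
  # same arithmetic path for the observed and enumerated statistics
  observed <- sum(y[group == 1]) / n1 -
    (total - sum(y[group == 1])) / (n_total - n1)
  assignments <- utils::combn(n_total, n1)
  s1 <- colSums(matrix(y[assignments], nrow = n1))
  stats_all <- s1 / n1 - (total - s1) / (n_total - n1)
  n_exceed <- count_exceedances(stats_all, observed, alternative)
  n_assign <- ncol(assignments)
  new_permutation_result(observed, n_exceed, n_assign, n_exceed / n_assign,
                         alternative, seed = NULL, mode = "exhaustive")
}

check_interaction_design <- function(y, ip, iq) {
  if (length(unique(c(length(y), length(ip), length(iq)))) != 1) {
    stop("`y`, `ip`, `iq` lengths differ")
  }
  if (!all(ip %in% c(0, 1)) || !all(iq %in% c(0, 1))) {
    stop("`ip` and `iq` must be 0/1 indicators")
  }
  invisible(NULL)
}

#' Fit the two-mutation interaction model
#'
#' Ordinary least squares of `Yj = b1*Ip,j + b2*Iq,j + b3*Ip,j*Iq,j + ej`
#' (no intercept), where `Ip` and `Iq` indicate heterozygosity for the two
#' mutations. With the usual three-group design (p-only, q-only, double
#' heterozygotes) the model is saturated: `b1` and `b2` are the single-
#' heterozygote group means and `b3` is the double-heterozygote mean minus the
#' additive expectation `b1 + b2`. Synergy (a more-than-additive double-
#' heterozygote phenotype) corresponds to `b3 > 0`.
#'
#' @param y Numeric response (per-embryo defect proportions).
#' @param ip,iq 0/1 indicators for heterozygosity of mutation p and q.
#' @param intercept Include an intercept term (off by default; the
#'   no-intercept parameterization pins the unmutated baseline at 0 and is the
#'   primary form — the intercept mode is a sensitivity analysis).
#' @return A list with `coefficients`, `residuals`, and `statistic` (= `b3`).
#' @examples
#' y <- c(0.10, 0.12, 0.20, 0.22, 0.38, 0.40)
#' fit_interaction(y, ip = c(1, 1, 0, 0, 1, 1), iq = c(0, 0, 1, 1, 1, 1))
#' @export
fit_interaction <- function(y, ip, iq, intercept = FALSE) {
  check_interaction_design(y, ip, iq)
  x <- cbind(b1 = ip, b2 = iq, b3 = ip * iq)
  if (intercept) x <- cbind(b0 = 1, x)
  fit <- stats::lm.fit(x, y)
  if (fit$rank < ncol(x)) {
    stop("rank-deficient design: every genotype group (p-only, q-only, ",
         "double) must be non-empty")
  }
  list(coefficients = fit$coefficients, residuals = fit$residuals,
       statistic = unname(fit$coefficients["b3"]))
}

#' Orthogonalize a covariate against nuisance columns (Smith procedure)
#'
#' Returns the residual of `z` after least-squares projection onto the
#' nuisance design `x_nuis`, i.e. `z - X (X'X)^{-1} X'z`. The result is
#' orthogonal to every nuisance column; permuting its entries while the
#' response and nuisance columns stay fixed is the Smith permutation strategy
#' for testing a single coefficient in a multiple regression.
#'
#' @param x_nuis Numeric matrix of nuisance covariates (full column rank).
#' @param z Numeric target covariate.
#' @return Numeric vector `z_res`, orthogonal to the columns of `x_nuis`.
#' @examples
#' x <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
#' smith_orthogonalize(x, c(1, 0, 0, 0))
#' @export
smith_orthogonalize <- function(x_nuis, z) {
  x_nuis <- as.matrix(x_nuis)
  if (length(z) != nrow(x_nuis)) stop("`z` length must match nrow(x_nuis)")
  qx <- qr(x_nuis)
  if (qx$rank < ncol(x_nuis)) {
    stop("nuisance columns are linearly dependent")
  }
  as.numeric(qr.resid(qx, z))
}

#' Smith-orthogonalization permutation test of the interaction coefficient
#'
#' Tests `H0: b3 = 0` in the no-intercept interaction model. The interaction
#' column `Ip*Iq` is first orthogonalized against the nuisance columns
#' `(Ip, Iq)` with [smith_orthogonalize()]; the observed statistic is the
#' coefficient of the orthogonalized column, which equals `b3` from the full
#' model. Each permutation shuffles the entries of the orthogonalized column
#' across embryos while the response and nuisance columns stay fixed, and the
#' coefficient is recomputed. `p = (n + 1) / (N + 1)` with the same
#' exceedance rule as the two-group test; the default alternative `"greater"`
#' matches synergy as an excess over additivity.
#'
#' @inheritParams fit_interaction
#' @inheritParams permutation_test_two_group
#' @return A `permutation_result` object.
#' @examples
#' set.seed(7)
#' ip <- rep(c(1, 0, 1), each = 6); iq <- rep(c(0, 1, 1), each = 6)
#' y <- 0.05 * ip + 0.05 * iq + 0.2 * ip * iq + abs(rnorm(18, 0, 0.02))
#' permutation_test_interaction(y, ip, iq, n_perm = 999, seed = 1)
#' @export
permutation_test_interaction <- function(y, ip, iq, n_perm = 1e6,
                                         alternative = c("greater", "less",
                                                         "two.sided"),
                                         seed = NULL) {
  alternative <- match.arg(alternative)
  check_interaction_design(y, ip, iq)
  fit_interaction(y, ip, iq)   # validates the three-group design
  if (n_perm < 1) stop("`n_perm` must be at least 1")
  n_perm <- as.integer(n_perm)
  if (!is.null(seed)) set.seed(seed)

  x_nuis <- cbind(ip, iq)
  z_res <- smith_orthogonalize(x_nuis, ip * iq)
  coef_on <- function(zmat) {
    # coefficient of each (permuted) column after re-residualizing on x_nuis
    proj <- x_nuis %*% solve(crossprod(x_nuis), crossprod(x_nuis, zmat))
    zperp <- zmat - proj
    denom <- colSums(zperp^2)
    num <- colSums(zperp * y)
    ifelse(denom > 0, num / denom, 0)
  }
  observed <- coef_on(matrix(z_res, ncol = 1))[1]

  n_total <- length(y)
  n_exceed <- 0L
  chunk <- 20000L
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    idx <- vapply(seq_len(b), function(i) sample.int(n_total), integer(n_total))
    stats_perm <- coef_on(matrix(z_res[idx], nrow = n_total))
    n_exceed <- n_exceed + count_exceedances(stats_perm, observed, alternative)
    done <- done + b
  }
  new_permutation_result(observed, n_exceed, n_perm,
                         (n_exceed + 1) / (n_perm + 1), alternative, seed)
}
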