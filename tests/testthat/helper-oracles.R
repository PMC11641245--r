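# Independent oracles and fixture builders used across the suite.

# Brute-force Svp-lineage oracle, coded independently of the package's
# enumeration: walks ordered per-progenitor outcome assignments for k = 1..3
# and derives category labels from the minimum-error assignments.
oracle_svp_flags <- function(s, q, e, enlarged_reliable = TRUE) {
  outcome_cc <- c(NORMAL = 1, BOTH_CC = 2, BOTH_PC = 0, KARYO = 1)
  outcome_pc <- c(NORMAL = 1, BOTH_CC = 0, BOTH_PC = 2, KARYO = 0)
  outcome_enl <- c(NORMAL = 0, BOTH_CC = 0, BOTH_PC = 0, KARYO = 1)
  hits <- list()
  for (k in 1:3) {
    grids <- do.call(expand.grid,
                     c(rep(list(names(outcome_cc)), k),
                       list(stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(grids))) {
      assignment <- unlist(grids[r, ], use.names = FALSE)
      cc <- sum(outcome_cc[assignment])
      pc <- sum(outcome_pc[assignment])
      enl <- sum(outcome_enl[assignment])
      ok_enl <- if (enlarged_reliable) enl == e else enl >= e
      if (cc == s && pc == q && ok_enl) {
        hits[[length(hits) + 1L]] <- list(
          k = k,
          weight = abs(k - 2) + sum(assignment != "NORMAL"),
          any_fail = any(assignment != "NORMAL")
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(list(asymmetric = NA, earlier = NA, svp_lineage = TRUE,
                inconsistent = TRUE))
  }
  weights <- vapply(hits, `[[`, numeric(1), "weight")
  minimal <- hits[weights == min(weights)]
  reduce <- function(v) if (all(v)) TRUE else if (!any(v)) FALSE else NA
  list(
    asymmetric = reduce(vapply(minimal, `[[`, logical(1), "any_fail")),
    earlier = reduce(vapply(minimal, `[[`, numeric(1), "k") != 2),
    svp_lineage = min(weights) > 0,
    inconsistent = FALSE
  )
}

# Independent OLS via the normal equations (not lm/qr), for cross-checks.
oracle_ols <- function(x, y) {
  solve(t(x) %*% x, t(x) %*% y)[, 1]
}

# Fast raw hemisegment draw (skips the tibble wrapper for Monte-Carlo loops).
draw_hemi_for_test <- function(rates, segment = "A3") {
  cardiodiv:::draw_hemisegment(segment, rates)
}

# Small hand-built counts table: 1 embryo, mixed defects and dropouts.
fixture_counts <- function() {
  tibble::tibble(
    embryo_id = "e1", genotype = "mut",
    segment = rep(paste0("A", 2:8), each = 2),
    side = rep(c("L", "R"), 7),
    n_tin_cc = c(4L, 4L, 5L, 4L, 4L, 4L, 4L, 3L, 4L, 4L, 4L, 4L, 2L, NA),
    n_svp_cc = c(2L, 2L, 2L, 3L, 2L, 2L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, NA),
    n_svp_pc = c(2L, 2L, 2L, 1L, 2L, 2L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, NA),
    n_enlarged_svp_cc = c(rep(0L, 13), NA),
    scoreable = c(rep(TRUE, 13), FALSE)
  )
}

# Three-group synergy cohort on the proportion scale.
fixture_interaction <- function(n_each = 6, means = c(p = 0.1, q = 0.2,
                                                      double = 0.35),
                                noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- c(rep(means[["p"]], n_each), rep(means[["q"]], n_each),
         rep(means[["double"]], n_each)) +
    stats::rnorm(3 * n_each, 0, noise)
  list(y = y,
       ip = rep(c(1, 0, 1), each = n_each),
       iq = rep(c(0, 1, 1), each = n_each))
}
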