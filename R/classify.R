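# Classification of per-hemisegment cell counts into cell-division defect
# categories. The Svp-lineage call works by exhaustively enumerating lineage
# explanations: how many Svp progenitors (k in 1..3) and which per-progenitor
# outcome (normal asymmetric division, both-CC, both-PC, karyokinesis failure)
# would reproduce the observed (n_svp_cc, n_svp_pc, n_enlarged_svp_cc) triple.

ASYM_OUTCOMES <- c("NORMAL", "BOTH_CC", "BOTH_PC", "KARYOKINESIS_FAIL")

#' Enumerate lineage explanations consistent with observed Svp-lineage counts
#'
#' Considers every progenitor count k in \{1, 2, 3\} and every assignment of
#' per-progenitor outcomes (NORMAL -> 1 CC + 1 PC; BOTH_CC -> 2 CC;
#' BOTH_PC -> 2 PC; KARYOKINESIS_FAIL -> 1 enlarged CC, no PC) and keeps those
#' whose predicted counts reproduce the observed triple. Each explanation
#' carries an error weight `|k - 2| + (number of non-NORMAL outcomes)`, the
#' number of division errors it posits.
#'
#' An empty result means no lineage explanation exists for the observation
#' (within k <= 3), which the classifier reports as `inconsistent`.
#'
#' @param n_svp_cc Observed number of Svp cardial cells.
#' @param n_svp_pc Observed number of Svp pericardial cells.
#' @param n_enlarged Observed number of enlarged-nucleus Svp-CCs.
#' @param enlarged_marker_reliable If `TRUE` (default) an explanation must
#'   predict exactly the observed number of enlarged nuclei; if `FALSE`,
#'   karyokinesis failures may go unobserved (microscopy can miss nuclear
#'   size), so explanations may predict more enlarged cells than seen.
#' @return A data.frame with one row per consistent explanation: `k`, outcome
#'   counts `n_normal`, `n_both_cc`, `n_both_pc`, `n_karyo`, and
#'   `error_weight`. Zero rows when the observation is inconsistent.
#' @examples
#' enumerate_consistent_explanations(2, 2, 0)  # unique wild-type explanation
#' enumerate_consistent_explanations(3, 1, 0)  # one progenitor made two CCs
#' @export
enumerate_consistent_explanations <- function(n_svp_cc, n_svp_pc, n_enlarged = 0,
                                              enlarged_marker_reliable = TRUE) {
  stopifnot(n_svp_cc >= 0, n_svp_pc >= 0, n_enlarged >= 0,
            n_enlarged <= n_svp_cc)
  rows <- list()
  for (k in 1:3) {
    # compositions of k over the four outcome types
    for (a in 0:k) for (b in 0:(k - a)) for (cc in 0:(k - a - b)) {
      d <- k - a - b - cc
      pred_cc <- a + 2L * b + d
      pred_pc <- a + 2L * cc
      pred_enl <- d
      enl_ok <- if (enlarged_marker_reliable) pred_enl == n_enlarged
                else pred_enl >= n_enlarged
      if (pred_cc == n_svp_cc && pred_pc == n_svp_pc && enl_ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, n_normal = a, n_both_cc = b, n_both_pc = cc, n_karyo = d,
          error_weight = abs(k - 2L) + (b + cc + d)
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(k = integer(), n_normal = integer(),
                      n_both_cc = integer(), n_both_pc = integer(),
                      n_karyo = integer(), error_weight = integer()))
  }
  do.call(rbind, rows)
}

# Reduce a logical vector of per-explanation verdicts to TRUE / FALSE / NA
# (NA = the minimal explanations disagree).
consensus_flag <- function(x) {
  if (all(x)) TRUE else if (!any(x)) FALSE else NA
}

#' Classify a hemisegment with full (pericardial-informed) information
#'
#' The symmetric-division call is direct: `n_tin_cc` differing from the
#' segment's expectation (4 in A2-A7, 2 in A8) flags a symmetric defect. The
#' Svp-lineage calls use [enumerate_consistent_explanations()]: among the
#' explanations positing the fewest division errors, an earlier-stage defect
#' is flagged when every minimal explanation needs a progenitor count other
#' than 2, and an asymmetric defect when every minimal explanation contains a
#' failed asymmetric division. When minimal explanations disagree the affected
#' flag is `NA` (recorded but not assigned), while `svp_lineage` is still
#' `TRUE`. Observations with no lineage explanation (e.g. a lone missing
#' pericardial cell under a reliable enlarged-nucleus marker) are flagged
#' `inconsistent`.
#'
#' @param segment Segment label (`"A2"` .. `"A8"`), used only for the expected
#'   Tin-CC count.
#' @param n_tin_cc,n_svp_cc,n_svp_pc,n_enlarged Observed counts.
#' @param enlarged_marker_reliable See [enumerate_consistent_explanations()].
#' @return A one-row tibble with logical (`NA`-able) columns `symmetric`,
#'   `asymmetric`, `earlier`, `svp_lineage`, `inconsistent`.
#' @examples
#' classify_hemisegment_full("A3", 4, 2, 2)      # wild type: no flags
#' classify_hemisegment_full("A3", 4, 3, 1)      # asymmetric defect
#' classify_hemisegment_full("A3", 4, 1, 1)      # earlier-stage defect
#' @export
classify_hemisegment_full <- function(segment, n_tin_cc, n_svp_cc, n_svp_pc,
                                      n_enlarged = 0,
                                      enlarged_marker_reliable = TRUE) {
  if (is.na(n_svp_pc)) {
    stop("pericardial counts are missing: use classify_hemisegment_cc_only()")
  }
  symmetric <- n_tin_cc != expected_tin_count(segment)
  expl <- enumerate_consistent_explanations(n_svp_cc, n_svp_pc, n_enlarged,
                                            enlarged_marker_reliable)
  if (nrow(expl) == 0) {
    return(tibble::tibble(symmetric = symmetric, asymmetric = NA,
                          earlier = NA, svp_lineage = TRUE,
                          inconsistent = TRUE))
  }
  minimal <- expl[expl$error_weight == min(expl$error_weight), , drop = FALSE]
  earlier <- consensus_flag(minimal$k != 2L)
  asymmetric <- consensus_flag(
    minimal$n_both_cc + minimal$n_both_pc + minimal$n_karyo > 0L
  )
  svp_lineage <- min(expl$error_weight) > 0L
  tibble::tibble(symmetric = symmetric, asymmetric = asymmetric,
                 earlier = earlier, svp_lineage = svp_lineage,
                 inconsistent = FALSE)
}

#' Classify a hemisegment from cardial-cell counts only
#'
#' When pericardial cells are not visualized, asymmetric and earlier-stage
#' defects cannot be distinguished: any deviation from the expected two
#' Svp-CCs flags a defect somewhere along the Svp lineage, and the specific
#' category is left unknown (`NA`).
#'
#' @inheritParams classify_hemisegment_full
#' @return A one-row tibble as in [classify_hemisegment_full()].
#' @examples
#' classify_hemisegment_cc_only("A3", 4, 3)  # Svp-lineage defect, type unknown
#' @export
classify_hemisegment_cc_only <- function(segment, n_tin_cc, n_svp_cc) {
  tibble::tibble(
    symmetric = n_tin_cc != expected_tin_count(segment),
    asymmetric = NA,
    earlier = NA,
    svp_lineage = n_svp_cc != 2L,
    inconsistent = FALSE
  )
}

#' Classify every scoreable hemisegment in a counts table
#'
#' Rows with missing `n_svp_pc` are classified with the cardial-cell-only
#' rules, other rows with the full (pericardial-informed) rules. Unscoreable
#' rows are dropped. Classification of repeated count patterns is cached, so
#' large cohorts classify quickly.
#'
#' @param counts Counts tibble (see [simulate_cohort()]).
#' @param enlarged_marker_reliable See [enumerate_consistent_explanations()].
#' @return A calls tibble: `embryo_id`, `genotype`, `segment`, `side`, and the
#'   five flag columns.
#' @export
classify_counts <- function(counts, enlarged_marker_reliable = TRUE) {
  keep <- counts[counts$scoreable & !is.na(counts$n_svp_cc), , drop = FALSE]
  if (nrow(keep) == 0) {
    return(tibble::tibble(embryo_id = character(), genotype = character(),
                          segment = character(), side = character(),
                          symmetric = logical(), asymmetric = logical(),
                          earlier = logical(), svp_lineage = logical(),
                          inconsistent = logical()))
  }
  key <- paste(keep$segment, keep$n_tin_cc, keep$n_svp_cc,
               ifelse(is.na(keep$n_svp_pc), ".", keep$n_svp_pc),
               keep$n_enlarged_svp_cc, sep = "|")
  uniq <- !duplicated(key)
  cache <- vector("list", sum(uniq))
  names(cache) <- key[uniq]
  for (i in which(uniq)) {
    cache[[key[i]]] <- if (is.na(keep$n_svp_pc[i])) {
      classify_hemisegment_cc_only(keep$segment[i], keep$n_tin_cc[i],
                                   keep$n_svp_cc[i])
    } else {
      classify_hemisegment_full(keep$segment[i], keep$n_tin_cc[i],
                                keep$n_svp_cc[i], keep$n_svp_pc[i],
                                keep$n_enlarged_svp_cc[i],
                                enlarged_marker_reliable)
    }
  }
  calls <- do.call(rbind, cache[key])
  tibble::tibble(
    embryo_id = keep$embryo_id, genotype = keep$genotype,
    segment = keep$segment, side = keep$side,
    symmetric = calls$symmetric, asymmetric = calls$asymmetric,
    earlier = calls$earlier, svp_lineage = calls$svp_lineage,
    inconsistent = calls$inconsistent
  )
}

DEFECT_CATEGORIES <- c("svp_lineage", "symmetric", "asymmetric", "earlier", "any")

#' Summarize defect proportions per embryo
#'
#' For each embryo, computes the proportion of scoreable hemisegments flagged
#' in each defect category; these proportions are the response variable of the
#' permutation-regression tests. Unknown (`NA`) asymmetric/earlier flags never
#' count as defects for their specific category, but the hemisegment still
#' counts toward `svp_lineage`. The `any` category flags hemisegments with a
#' defect in either lineage. Embryos with zero scoreable hemisegments are
#' excluded with a warning.
#'
#' @param calls Calls tibble from [classify_counts()].
#' @param counts Optional counts tibble, used to report embryos whose every
#'   hemisegment was unscoreable (they never reach `calls`).
#' @return A tibble: `embryo_id`, `genotype`, `n_scoreable`, and one
#'   proportion column `p_<category>` per category.
#' @export
summarize_embryos <- function(calls, counts = NULL) {
  if (!is.null(counts)) {
    lost <- setdiff(unique(counts$embryo_id), unique(calls$embryo_id))
    if (length(lost) > 0) {
      warning("excluding embryo(s) with zero scoreable hemisegments: ",
              paste(lost, collapse = ", "))
    }
  }
  ids <- unique(calls$embryo_id)
  out <- lapply(ids, function(id) {
    e <- calls[calls$embryo_id == id, , drop = FALSE]
    n <- nrow(e)
    tibble::tibble(
      embryo_id = id,
      genotype = e$genotype[1],
      n_scoreable = n,
      p_svp_lineage = sum(e$svp_lineage, na.rm = TRUE) / n,
      p_symmetric = sum(e$symmetric, na.rm = TRUE) / n,
      p_asymmetric = sum(e$asymmetric %in% TRUE) / n,
      p_earlier = sum(e$earlier %in% TRUE) / n,
      p_any = sum(e$svp_lineage | e$symmetric, na.rm = TRUE) / n
    )
  })
  do.call(rbind, out)
}

#' Defect proportion of a single embryo in one category
#'
#' Convenience wrapper around [summarize_embryos()] for one embryo's calls.
#'
#' @param calls Calls tibble for a single embryo.
#' @param category One of `"svp_lineage"`, `"symmetric"`, `"asymmetric"`,
#'   `"earlier"`, `"any"`.
#' @return The proportion of scoreable hemisegments flagged in `category`.
#' @export
summarize_embryo <- function(calls, category = "any") {
  category <- match.arg(category, DEFECT_CATEGORIES)
  if (nrow(calls) == 0) {
    warning("embryo has zero scoreable hemisegments; proportion undefined")
    return(NA_real_)
  }
  summ <- summarize_embryos(calls)
  summ[[paste0("p_", category)]][1]
}
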