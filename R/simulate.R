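# Lineage simulator for the scored region of the embryonic heart tube
# (abdominal hemisegments A2-A8, left and right).

SEGMENTS <- paste0("A", 2:8)
SIDES <- c("L", "R")

#' Expected Tin-CC count for a hemisegment
#'
#' The stereotyped wild-type pattern carries four Tin cardial cells per
#' hemisegment in A2-A7 and two in the truncated A8.
#'
#' @param segment Character vector of segment labels (`"A2"` .. `"A8"`).
#'   Missing labels default to the A2-A7 expectation of 4, with a warning.
#' @return Integer vector of expected Tin-CC counts.
#' @export
expected_tin_count <- function(segment) {
  out <- rep(4L, length(segment))
  missing <- is.na(segment)
  if (any(missing)) {
    warning("missing segment labels: assuming the A2-A7 expectation of 4 Tin-CCs")
  }
  bad <- !missing & !(segment %in% SEGMENTS)
  if (any(bad)) {
    stop("invalid segment label(s): ", paste(unique(segment[bad]), collapse = ", "))
  }
  out[!missing & segment == "A8"] <- 2L
  out
}

#' Simulate cell counts for one cardiac hemisegment
#'
#' Draws one hemisegment from the lineage model. The Svp lineage starts from
#' an earlier-stage division yielding k progenitors (2 with probability
#' `1 - r_early`, otherwise 1 or 3 with equal probability); each progenitor
#' then divides asymmetrically into one Svp-CC and one Svp-PC, or fails with
#' probability `r_asym` into one of three modes: two CCs, two PCs, or a single
#' enlarged-nucleus CC whose PC is lost to karyokinesis failure. The Tin
#' lineage has two progenitors in A2-A7 (one in A8), each dividing
#' symmetrically into two Tin-CCs or failing with probability `r_sym` into one
#' or three cells.
#'
#' Uses R's global random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param segment Segment label, one of `"A2"` .. `"A8"`.
#' @param rates A [division_error_rates()] object.
#' @param side Side label, `"L"` or `"R"`.
#' @return A one-row [tibble::tibble] with columns `segment`, `side`,
#'   `n_tin_cc`, `n_svp_cc`, `n_svp_pc`, `n_enlarged_svp_cc`, `scoreable`.
#' @examples
#' set.seed(1)
#' simulate_hemisegment("A3", division_error_rates())
#' @export
simulate_hemisegment <- function(segment, rates, side = "L") {
  validate_rates(rates)
  if (length(segment) != 1 || !(segment %in% SEGMENTS)) {
    stop("`segment` must be one of ", paste(SEGMENTS, collapse = ", "))
  }
  if (!(side %in% SIDES)) stop("`side` must be 'L' or 'R'")
  counts <- draw_hemisegment(segment, rates)
  tibble::tibble(
    segment = segment, side = side,
    n_tin_cc = counts[["n_tin_cc"]],
    n_svp_cc = counts[["n_svp_cc"]],
    n_svp_pc = counts[["n_svp_pc"]],
    n_enlarged_svp_cc = counts[["n_enlarged_svp_cc"]],
    scoreable = TRUE
  )
}

# Internal single-hemisegment draw; returns an integer vector.
draw_hemisegment <- function(segment, rates) {
  # Earlier-stage division: number of Svp progenitors
  k <- if (stats::runif(1) < rates$r_early) {
    if (stats::runif(1) < 0.5) 1L else 3L
  } else 2L

  n_svp_cc <- 0L
  n_svp_pc <- 0L
  n_enl <- 0L
  for (i in seq_len(k)) {
    if (stats::runif(1) < rates$r_asym) {
      mode <- sample.int(3L, 1L, prob = rates$asym_mode_weights)
      if (mode == 1L) {                 # both daughters become CCs
        n_svp_cc <- n_svp_cc + 2L
      } else if (mode == 2L) {          # both daughters become PCs
        n_svp_pc <- n_svp_pc + 2L
      } else {                          # karyokinesis failure: one enlarged CC
        n_svp_cc <- n_svp_cc + 1L
        n_enl <- n_enl + 1L
      }
    } else {
      n_svp_cc <- n_svp_cc + 1L
      n_svp_pc <- n_svp_pc + 1L
    }
  }

  n_tin_prog <- if (segment == "A8") 1L else 2L
  n_tin_cc <- 0L
  for (i in seq_len(n_tin_prog)) {
    if (stats::runif(1) < rates$r_sym) {
      mode <- sample.int(2L, 1L, prob = rates$sym_mode_weights)
      n_tin_cc <- n_tin_cc + (if (mode == 1L) 1L else 3L)
    } else {
      n_tin_cc <- n_tin_cc + 2L
    }
  }

  c(n_tin_cc = n_tin_cc, n_svp_cc = n_svp_cc, n_svp_pc = n_svp_pc,
    n_enlarged_svp_cc = n_enl)
}

#' Simulate one embryo (14 hemisegments, A2-A8 x L/R)
#'
#' Each hemisegment is drawn independently from the lineage model and
#' independently marked unscoreable with probability `r_dropout`; unscoreable
#' hemisegments carry no counts (NA) and are excluded from all downstream
#' denominators.
#'
#' @inheritParams simulate_hemisegment
#' @param genotype Genotype label for the embryo.
#' @param embryo_id Identifier; defaults to the genotype with suffix `"_1"`.
#' @return A 14-row counts tibble (columns as in [simulate_hemisegment()],
#'   plus `embryo_id` and `genotype`).
#' @examples
#' set.seed(1)
#' emb <- simulate_embryo("wild_type", division_error_rates())
#' sum(emb$n_tin_cc)  # 52 in the error-free pattern
#' @export
simulate_embryo <- function(genotype, rates, embryo_id = paste0(genotype, "_1")) {
  validate_rates(rates)
  n <- length(SEGMENTS) * length(SIDES)
  seg <- rep(SEGMENTS, each = length(SIDES))
  sid <- rep(SIDES, times = length(SEGMENTS))
  tin <- svp <- pc <- enl <- integer(n)
  scoreable <- stats::runif(n) >= rates$r_dropout
  for (i in seq_len(n)) {
    if (scoreable[i]) {
      counts <- draw_hemisegment(seg[i], rates)
      tin[i] <- counts[["n_tin_cc"]]
      svp[i] <- counts[["n_svp_cc"]]
      pc[i] <- counts[["n_svp_pc"]]
      enl[i] <- counts[["n_enlarged_svp_cc"]]
    } else {
      tin[i] <- svp[i] <- pc[i] <- enl[i] <- NA_integer_
    }
  }
  tibble::tibble(
    embryo_id = embryo_id, genotype = genotype,
    segment = seg, side = sid,
    n_tin_cc = tin, n_svp_cc = svp, n_svp_pc = pc, n_enlarged_svp_cc = enl,
    scoreable = scoreable
  )
}

# Deterministic 31-bit stream seed from (cohort seed, genotype, embryo index),
# so cohorts are reproducible and embryo order-independent.
substream_seed <- function(seed, genotype, index) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(genotype)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  h <- (h * 131 + index) %% 2147483647
  as.integer(h)
}

#' Simulate a cohort of embryos across genotypes
#'
#' @param design Named list mapping genotype label to
#'   `list(n_embryos = <int>, rates = <division_error_rates>)`.
#' @param seed Integer seed. Each embryo is drawn from its own RNG substream
#'   keyed by `(seed, genotype, embryo index)`, so the same design and seed
#'   always reproduce the same table regardless of genotype order.
#' @return A counts tibble with one row per hemisegment
#'   (`n_embryos x 14` rows per genotype).
#' @examples
#' design <- list(
#'   wild_type = list(n_embryos = 3, rates = division_error_rates()),
#'   mutant = list(n_embryos = 3, rates = division_error_rates(r_sym = 0.3))
#' )
#' counts <- simulate_cohort(design, seed = 42)
#' @export
simulate_cohort <- function(design, seed) {
  if (is.null(names(design)) || anyDuplicated(names(design))) {
    stop("`design` must be a named list with unique genotype labels")
  }
  pieces <- list()
  for (genotype in names(design)) {
    spec <- design[[genotype]]
    if (is.null(spec$n_embryos) || spec$n_embryos < 1) {
      stop("genotype '", genotype, "' must request at least one embryo")
    }
    validate_rates(spec$rates)
    for (i in seq_len(spec$n_embryos)) {
      set.seed(substream_seed(seed, genotype, i))
      pieces[[length(pieces) + 1L]] <- simulate_embryo(
        genotype, spec$rates, embryo_id = sprintf("%s_%02d", genotype, i)
      )
    }
  }
  do.call(rbind, pieces)
}

#' Mask pericardial-cell information from a counts table
#'
#' Emulates scoring with Mef2/Svp antibodies only (no svp-lacZ enhancer trap):
#' Svp pericardial cells are not visualized and enlarged-nucleus calls cannot
#' be made. Sets `n_svp_pc` to missing and `n_enlarged_svp_cc` to 0 in every
#' row. Idempotent.
#'
#' @param counts A counts tibble (from [simulate_cohort()] or
#'   [read_counts_table()]).
#' @return The masked counts tibble.
#' @export
mask_pericardial <- function(counts) {
  counts$n_svp_pc <- NA_integer_
  counts$n_enlarged_svp_cc <- ifelse(is.na(counts$n_svp_cc), NA_integer_, 0L)
  counts
}
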