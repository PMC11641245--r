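# End-to-end orchestration: simulate (or read) a cohort, classify and
# summarize it, and run the configured permutation tests; optionally gate a
# DE table. Deterministic given (config, seed).

#' Pooled per-genotype defect percentages
#'
#' Aggregates per-embryo summaries into the per-genotype presentation used in
#' phenotypic screens: number of embryos, number of scoreable hemisegments,
#' and the pooled percentage of hemisegments flagged in each category (total
#' flagged / total scoreable, i.e. the hemisegment-weighted mean of the
#' per-embryo proportions).
#'
#' @param summaries Per-embryo summary tibble from [summarize_embryos()].
#' @return A tibble: `genotype`, `n_embryos`, `n_hemisegments`, and one
#'   `pct_<category>` column per category (percent scale).
#' @export
summarize_cohort <- function(summaries) {
  if (nrow(summaries) == 0) stop("no embryo summaries supplied")
  out <- lapply(unique(summaries$genotype), function(g) {
    s <- summaries[summaries$genotype == g, , drop = FALSE]
    n_hemi <- sum(s$n_scoreable)
    pooled <- function(col) 100 * sum(s[[col]] * s$n_scoreable) / n_hemi
    tibble::tibble(
      genotype = g,
      n_embryos = nrow(s),
      n_hemisegments = n_hemi,
      pct_svp_lineage = pooled("p_svp_lineage"),
      pct_symmetric = pooled("p_symmetric"),
      pct_asymmetric = pooled("p_asymmetric"),
      pct_earlier = pooled("p_earlier"),
      pct_any = pooled("p_any")
    )
  })
  do.call(rbind, out)
}

rates_from_config <- function(x) {
  if (is.null(x)) return(division_error_rates())
  known <- c("r_early", "r_asym", "asym_mode_weights", "r_sym",
             "sym_mode_weights", "r_dropout")
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) stop("unknown rate field(s): ", paste(bad, collapse = ", "))
  do.call(division_error_rates, x)
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (typically read from a YAML file) with:
#' \describe{
#'   \item{cohort}{Either `counts_path` (a counts TSV) or `genotypes`, a named
#'     map of `genotype: \{n_embryos, rates\}` blocks for the simulator.}
#'   \item{categories}{Defect categories to test (default
#'     `c("svp_lineage", "symmetric")`).}
#'   \item{comparisons}{`two_group`: list of `\{ref, alt\}` genotype pairs;
#'     `interaction`: list of `\{p, q, double\}` genotype triples.}
#'   \item{n_perm, alternative}{Permutation settings (defaults `1e6`,
#'     `"greater"`).}
#' }
#'
#' @param config Named list.
#' @return The config with defaults filled in; errors on inconsistency.
#' @export
validate_config <- function(config) {
  if (is.null(config$cohort)) stop("config needs a `cohort` block")
  has_path <- !is.null(config$cohort$counts_path)
  has_design <- !is.null(config$cohort$genotypes)
  if (!has_path && !has_design) {
    stop("`cohort` needs either `counts_path` or `genotypes`")
  }
  config$categories <- config$categories %||% c("svp_lineage", "symmetric")
  bad <- setdiff(config$categories, DEFECT_CATEGORIES)
  if (length(bad) > 0) stop("unknown categories: ", paste(bad, collapse = ", "))
  config$n_perm <- config$n_perm %||% 1e6
  if (config$n_perm < 1) stop("`n_perm` must be at least 1")
  config$alternative <- config$alternative %||% "greater"
  config$mask_pericardial <- isTRUE(config$mask_pericardial)

  known_genotypes <- if (has_design) names(config$cohort$genotypes) else NULL
  check_genotype <- function(g, where) {
    if (has_design && !(g %in% known_genotypes)) {
      stop("comparison ", where, " references undefined genotype '", g, "'")
    }
  }
  for (cmp in config$comparisons$two_group) {
    if (is.null(cmp$ref) || is.null(cmp$alt)) {
      stop("two-group comparisons need `ref` and `alt` genotypes")
    }
    check_genotype(cmp$ref, "two_group")
    check_genotype(cmp$alt, "two_group")
  }
  for (cmp in config$comparisons$interaction) {
    if (is.null(cmp$p) || is.null(cmp$q) || is.null(cmp$double)) {
      stop("interaction comparisons need `p`, `q`, and `double` genotypes")
    }
    for (g in c(cmp$p, cmp$q, cmp$double)) check_genotype(g, "interaction")
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a hemisegment counts table, classifies every
#' scoreable hemisegment, summarizes defect proportions per embryo and per
#' genotype, and runs the configured permutation tests. All stage tables are
#' returned and, when `out_dir` is given, written as TSV. Deterministic given
#' `(config, seed)`.
#'
#' @param config Configuration list (see [validate_config()]) or path to a
#'   YAML file.
#' @param seed Integer seed used for the cohort simulation and the
#'   permutation shuffles.
#' @param out_dir Optional output directory for the stage TSVs
#'   (`counts.tsv`, `calls.tsv`, `embryo_summary.tsv`, `cohort_summary.tsv`,
#'   `tests.tsv`) and a plain-text `run_log.txt`.
#' @return A list (`run_report`) with `counts`, `calls`, `embryo_summary`,
#'   `cohort_summary`, `tests` (one row per comparison x category), and
#'   `provenance`.
#' @examples
#' config <- list(
#'   cohort = list(genotypes = list(
#'     wild_type = list(n_embryos = 6, rates = list()),
#'     mutant = list(n_embryos = 6, rates = list(r_asym = 0.3))
#'   )),
#'   comparisons = list(two_group = list(list(ref = "wild_type",
#'                                            alt = "mutant"))),
#'   n_perm = 199
#' )
#' report <- run_pipeline(config, seed = 11)
#' report$tests
#' @export
run_pipeline <- function(config, seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  log_lines <- c(sprintf("cardiodiv run, seed = %d", as.integer(seed)),
                 sprintf("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))

  if (!is.null(config$cohort$counts_path)) {
    counts <- read_counts_table(config$cohort$counts_path)
    log_lines <- c(log_lines,
                   sprintf("counts read from %s (%d rows)",
                           config$cohort$counts_path, nrow(counts)))
  } else {
    design <- lapply(config$cohort$genotypes, function(g) {
      list(n_embryos = g$n_embryos, rates = rates_from_config(g$rates))
    })
    counts <- simulate_cohort(design, seed = seed)
    log_lines <- c(log_lines,
                   sprintf("simulated %d genotypes, %d hemisegment rows",
                           length(design), nrow(counts)))
  }
  if (config$mask_pericardial) counts <- mask_pericardial(counts)

  calls <- classify_counts(counts)
  summaries <- withCallingHandlers(
    summarize_embryos(calls, counts),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  cohort_summary <- summarize_cohort(summaries)

  tests <- list()
  perm_seed <- substream_seed(seed, "permutation", 1)
  for (cmp in config$comparisons$two_group) {
    for (category in config$categories) {
      col <- paste0("p_", category)
      s <- summaries[summaries$genotype %in% c(cmp$ref, cmp$alt), , drop = FALSE]
      res <- permutation_test_two_group(
        s[[col]], as.integer(s$genotype == cmp$alt),
        n_perm = config$n_perm, alternative = config$alternative,
        seed = perm_seed
      )
      perm_seed <- perm_seed + 1L
      tests[[length(tests) + 1L]] <- tibble::tibble(
        comparison = paste(cmp$alt, "vs", cmp$ref), model = "two_group",
        category = category, statistic = res$statistic, n = res$n,
        n_perm = res$n_perm, p = res$p, alternative = res$alternative,
        seed = res$seed, mode = res$mode
      )
    }
  }
  for (cmp in config$comparisons$interaction) {
    for (category in config$categories) {
      col <- paste0("p_", category)
      s <- summaries[summaries$genotype %in% c(cmp$p, cmp$q, cmp$double), ,
                     drop = FALSE]
      ip <- as.integer(s$genotype %in% c(cmp$p, cmp$double))
      iq <- as.integer(s$genotype %in% c(cmp$q, cmp$double))
      res <- permutation_test_interaction(
        s[[col]], ip, iq, n_perm = config$n_perm,
        alternative = config$alternative, seed = perm_seed
      )
      perm_seed <- perm_seed + 1L
      tests[[length(tests) + 1L]] <- tibble::tibble(
        comparison = paste(cmp$double, "vs", cmp$p, "+", cmp$q),
        model = "interaction", category = category,
        statistic = res$statistic, n = res$n, n_perm = res$n_perm, p = res$p,
        alternative = res$alternative, seed = res$seed, mode = res$mode
      )
    }
  }
  tests <- if (length(tests) > 0) do.call(rbind, tests) else
    tibble::tibble(comparison = character(), model = character(),
                   category = character(), statistic = numeric(),
                   n = integer(), n_perm = integer(), p = numeric(),
                   alternative = character(), seed = integer(),
                   mode = character())

  report <- list(
    counts = counts, calls = calls, embryo_summary = summaries,
    cohort_summary = cohort_summary, tests = tests,
    provenance = list(seed = as.integer(seed),
                      n_perm = config$n_perm,
                      alternative = config$alternative,
                      version = as.character(utils::packageVersion("cardiodiv")))
  )
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts_table(counts, file.path(out_dir, "counts.tsv"))
    write_tsv_plain(calls, file.path(out_dir, "calls.tsv"))
    write_tsv_plain(summaries, file.path(out_dir, "embryo_summary.tsv"))
    write_tsv_plain(cohort_summary, file.path(out_dir, "cohort_summary.tsv"))
    write_tsv_plain(tests, file.path(out_dir, "tests.tsv"))
    log_lines <- c(log_lines,
                   sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("cardiodiv run report\n")
  cat(sprintf("  seed %d, %d permutations, alternative '%s'\n",
              x$provenance$seed, x$provenance$n_perm,
              x$provenance$alternative))
  cat("\nPer-genotype defect percentages:\n")
  print(as.data.frame(x$cohort_summary), row.names = FALSE, digits = 3)
  if (nrow(x$tests) > 0) {
    cat("\nPermutation tests:\n")
    print(as.data.frame(x$tests[, c("comparison", "model", "category",
                                    "statistic", "p")]),
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}
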