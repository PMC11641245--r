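# Expression-side bookkeeping: threshold gating of differential-expression
# results into Jumu-activated/repressed sets, the low-expression exclusion,
# and RT-qPCR 2^-ddCT relative quantification with one-tailed Welch tests.

#' Published differential expression of 21 Jumu-activated cell-division genes
#'
#' Differential-expression results (jumu-deficient vs wild-type Drosophila
#' mesodermal cells) for the 21 Jumu-activated genes selected for phenotypic
#' analysis of cardiac progenitor cell division. Negative `log2fc` means the
#' gene is activated by Jumu (expression drops when jumu is removed).
#'
#' @return A tibble with columns `gene`, `log2fc`, `pvalue`, `fdr`.
#' @examples
#' de <- jumu_mesoderm_de()
#' nrow(de)  # 21
#' @export
jumu_mesoderm_de <- function() {
  path <- system.file("extdata", "jumu_mesoderm_de.tsv", package = "cardiodiv",
                      mustWork = TRUE)
  read_de_table(path)
}

#' Read a differential-expression table
#'
#' @param path TSV/CSV file with columns `gene`, `log2fc`, `pvalue`, `fdr`,
#'   and optionally `log2cpm`. The delimiter is inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return A tibble of gene records in input order.
#' @export
read_de_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  needed <- c("gene", "log2fc", "fdr")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("DE table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Exclude the lowest-expressed fraction of genes
#'
#' Removes the `floor(fraction * n)` records with the lowest `log2cpm`
#' (log2 counts-per-million after normalization), the standard low-count
#' exclusion before threshold gating. Ties are broken by stable input order,
#' so with all-equal expression the earliest records are removed.
#'
#' @param records DE tibble carrying a `log2cpm` column.
#' @param fraction Fraction to remove, in `[0, 1)`; default 0.30.
#' @return The retained records, in input order.
#' @examples
#' de <- tibble::tibble(gene = letters[1:10], log2fc = 0, fdr = 1,
#'                      log2cpm = 10:1)
#' nrow(low_expression_filter(de, 0.30))  # 7
#' @export
low_expression_filter <- function(records, fraction = 0.30) {
  if (!("log2cpm" %in% names(records)) || anyNA(records$log2cpm)) {
    stop("`records` must carry a complete `log2cpm` column")
  }
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)")
  n_drop <- floor(fraction * nrow(records))
  if (n_drop == 0) return(records)
  ord <- order(records$log2cpm, seq_len(nrow(records)))
  drop_idx <- ord[seq_len(n_drop)]
  records[-drop_idx, , drop = FALSE]
}

#' Gate a differential-expression table into activated and repressed sets
#'
#' Applies the fold-change/FDR thresholds: a gene is *activated* by the factor
#' when `log2fc < -threshold` and `fdr < fdr_cutoff`, and *repressed* when
#' `log2fc > threshold` and `fdr < fdr_cutoff` (mutant-vs-wild-type contrast:
#' expression of an activated gene drops in the mutant). All inequalities are
#' strict; boundary values are excluded.
#'
#' @param records DE tibble (see [read_de_table()]).
#' @param stringency `"stringent"` (threshold 1), `"relaxed"` (threshold 0.5),
#'   or a positive numeric threshold.
#' @param fdr_cutoff FDR cutoff (default 0.1, strict).
#' @param activated_negative If `TRUE` (default) negative fold changes mark
#'   activated genes (mutant-vs-wild-type contrast); set `FALSE` for the
#'   opposite contrast orientation.
#' @return A list with tibbles `activated` and `repressed` (disjoint) and the
#'   numeric `threshold` used.
#' @examples
#' gates <- gate_de(jumu_mesoderm_de(), "relaxed")
#' nrow(gates$activated)  # all 21 genes pass the relaxed activation gate
#' @export
gate_de <- function(records, stringency = c("stringent", "relaxed"),
                    fdr_cutoff = 0.1, activated_negative = TRUE) {
  threshold <- if (is.numeric(stringency)) {
    stringency
  } else {
    switch(match.arg(stringency), stringent = 1, relaxed = 0.5)
  }
  if (threshold <= 0) stop("`stringency` threshold must be positive")
  lfc <- if (activated_negative) records$log2fc else -records$log2fc
  pass_fdr <- records$fdr < fdr_cutoff
  list(
    activated = records[lfc < -threshold & pass_fdr, , drop = FALSE],
    repressed = records[lfc > threshold & pass_fdr, , drop = FALSE],
    threshold = threshold
  )
}

#' Relative expression by the 2^-ddCT method
#'
#' Computes `dCT = CT_target - CT_reference` within each condition,
#' `ddCT = dCT_test - dCT_control`, and returns `2^-ddCT`, the expression of
#' the test condition relative to control after normalization to the
#' reference gene. Vectors of technical-replicate CT values are averaged on
#' the CT scale before differencing.
#'
#' @param test_ct_target,test_ct_ref CT values in the test condition.
#' @param ctrl_ct_target,ctrl_ct_ref CT values in the control condition.
#' @return Relative fold change (1 = no change, 0.5 = halved expression).
#' @examples
#' ddct_relative_expression(25, 20, 24, 20)  # 0.5
#' @export
ddct_relative_expression <- function(test_ct_target, test_ct_ref,
                                     ctrl_ct_target, ctrl_ct_ref) {
  cts <- c(test_ct_target, test_ct_ref, ctrl_ct_target, ctrl_ct_ref)
  if (anyNA(cts) || any(!is.finite(cts))) stop("CT values must be finite")
  dct_test <- mean(test_ct_target) - mean(test_ct_ref)
  dct_ctrl <- mean(ctrl_ct_target) - mean(ctrl_ct_ref)
  2^-(dct_test - dct_ctrl)
}

#' One-tailed Welch two-sample t-test
#'
#' Unequal-variance (heteroscedastic) t-test with Welch-Satterthwaite degrees
#' of freedom, returning the one-tailed p-value in the stated direction.
#'
#' @param x,y Numeric samples (each at least two values).
#' @param direction `"less"` tests whether the mean of `x` is below that of
#'   `y` (the usual direction for a knockdown), `"greater"` the reverse.
#' @return The one-tailed p-value.
#' @examples
#' welch_one_tailed(c(1, 2, 3), c(1, 2, 3))  # 0.5
#' @export
welch_one_tailed <- function(x, y, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least two values")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(0.5)
    stop("zero variance in both samples with unequal means")
  }
  stats::t.test(x, y, alternative = direction, var.equal = FALSE)$p.value
}

#' Per-gene qPCR analysis: fold change and one-tailed Welch test
#'
#' For each gene in a long-format qPCR table, averages technical-replicate CT
#' values on the CT scale within each (condition, replicate), computes the
#' 2^-ddCT fold change of test vs control from condition means, and tests the
#' per-replicate dCT values (test vs control) with a one-tailed Welch t-test.
#' `direction = "greater"` on the dCT scale corresponds to reduced expression
#' in the test condition (higher CT = less template).
#'
#' @param qpcr Tibble with columns `gene`, `condition` (`"control"`/`"test"`),
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param direction Direction of the alternative on the dCT scale
#'   (default `"greater"`: test expression lower than control).
#' @return A tibble: `gene`, `fold_change`, `p`.
#' @export
analyze_qpcr <- function(qpcr, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  needed <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
  if (!all(needed %in% names(qpcr))) {
    stop("qPCR table needs columns: ", paste(needed, collapse = ", "))
  }
  out <- lapply(unique(qpcr$gene), function(g) {
    d <- qpcr[qpcr$gene == g, , drop = FALSE]
    # technical replicates averaged on the CT scale within (condition, replicate)
    agg <- stats::aggregate(cbind(ct_target, ct_reference) ~ condition + replicate,
                            data = d, FUN = mean)
    dct <- agg$ct_target - agg$ct_reference
    is_test <- agg$condition == "test"
    if (!any(is_test) || !any(!is_test)) {
      stop("gene '", g, "' needs both control and test conditions")
    }
    fc <- 2^-(mean(dct[is_test]) - mean(dct[!is_test]))
    p <- if (sum(is_test) >= 2 && sum(!is_test) >= 2) {
      welch_one_tailed(dct[is_test], dct[!is_test], direction = direction)
    } else NA_real_
    tibble::tibble(gene = g, fold_change = fc, p = p)
  })
  do.call(rbind, out)
}
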