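# TSV interchange for the pipeline stages. The counts schema is the contract
# between the simulator, the classifier, and external scoring data: one
# hemisegment per row, blank n_svp_pc = pericardial cells not visualized.

COUNTS_COLUMNS <- c("embryo_id", "genotype", "segment", "side", "n_tin_cc",
                    "n_svp_cc", "n_svp_pc", "n_enlarged_svp_cc", "scoreable")

#' Write a hemisegment counts table as TSV
#'
#' UTF-8, tab-delimited, one hemisegment per row; missing pericardial counts
#' are written as empty fields and `scoreable` as 0/1.
#'
#' @param counts Counts tibble (see [simulate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  missing_cols <- setdiff(COUNTS_COLUMNS, names(counts))
  if (length(missing_cols) > 0) {
    stop("counts table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(counts[, COUNTS_COLUMNS])
  out$scoreable <- as.integer(out$scoreable)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a hemisegment counts table from TSV
#'
#' Validates the schema and restores missing pericardial counts from blank
#' fields. Lossless inverse of [write_counts_table()].
#'
#' @param path TSV path.
#' @return A counts tibble.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = "")
  missing_cols <- setdiff(COUNTS_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("counts file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), COUNTS_COLUMNS)
  if (length(extra) > 0) {
    stop("counts file has unknown column(s): ", paste(extra, collapse = ", "))
  }
  for (col in c("n_tin_cc", "n_svp_cc", "n_svp_pc", "n_enlarged_svp_cc")) {
    v <- df[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      stop("non-integer values in column: ", col)
    }
    if (is.numeric(v) && any(v[!is.na(v)] != as.integer(v[!is.na(v)]))) {
      stop("non-integer values in column: ", col)
    }
    df[[col]] <- as.integer(v)
  }
  df$scoreable <- as.logical(df$scoreable)
  df$embryo_id <- as.character(df$embryo_id)
  df$genotype <- as.character(df$genotype)
  df$segment <- as.character(df$segment)
  df$side <- as.character(df$side)
  tibble::as_tibble(df[, COUNTS_COLUMNS])
}

write_tsv_plain <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     na = "NA", row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
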