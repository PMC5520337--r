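# Column schemas for every table the pipeline reads or writes. Readers are
# header-keyed: column order in the file does not matter, names do.
table_schemas <- list(
  catalog = c("ase_id", "gene", "size_inclusion_bp", "size_exclusion_bp",
              "inclusion_is_long"),
  samples = c("sample_id", "cell_line", "condition", "batch_day"),
  peaks = c("sample_id", "ase_id", "called_size_bp", "area"),
  psi = c("ase_id", "cell_line", "condition", "batch_day", "psi",
          "inclusion_molar", "exclusion_molar", "n_extra_peaks"),
  delta_psi = c("ase_id", "cell_line", "sirna", "batch_day", "delta_psi"),
  calls = c("ase_id", "cell_line", "dpsi1", "dpsi2", "changed", "direction",
            "reason"),
  kd = c("cell_line", "sirna", "kd_fraction"),
  truth = c("ase_id", "gene", "cell_line", "baseline_psi", "effect_dpsi",
            "concordant"),
  enrichment = c("set", "k", "K", "n", "N", "p_value", "p_adjust", "genes")
)

#' Read a pipeline TSV table with schema validation
#'
#' Tables are tab-separated with a header row; missing values are `NA`.
#' Columns may appear in any order but every schema column must be present;
#' extra columns are dropped. A file whose header does not contain the
#' schema (for instance because it uses a different delimiter) is rejected
#' with the column difference.
#'
#' @param path TSV path.
#' @param schema one of `"catalog"`, `"samples"`, `"peaks"`, `"psi"`,
#'   `"delta_psi"`, `"calls"`, `"kd"`, `"truth"`, `"enrichment"`.
#' @return data.frame with the schema's columns in schema order.
#' @export
read_screen_table <- function(path, schema) {
  cols <- table_schemas[[match.arg(schema, names(table_schemas))]]
  if (!file.exists(path)) stop("table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(sprintf("%s does not match the '%s' schema; missing columns: %s (found: %s)",
                 path, schema, paste(missing_cols, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  df[, cols, drop = FALSE]
}

#' Write a pipeline TSV table
#'
#' Validates the data.frame against the schema, then writes a header-keyed
#' TSV with `NA` for missing values and no quoting.
#'
#' @param df data.frame carrying at least the schema's columns.
#' @param path output path.
#' @inheritParams read_screen_table
#' @return invisibly, `path`.
#' @export
write_screen_table <- function(df, path, schema) {
  cols <- table_schemas[[match.arg(schema, names(table_schemas))]]
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(sprintf("data does not match the '%s' schema; missing columns: %s",
                 schema, paste(missing_cols, collapse = ", ")), call. = FALSE)
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a trace to TSV
#'
#' Two columns, `time` and `signal`, one row per grid point.
#'
#' @param trace a `ce_trace`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(data.frame(time = trace$time, signal = trace$signal),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace from TSV
#'
#' @param path TSV with columns `time` and `signal`.
#' @param metadata optional list with `cell_line`, `condition`, `batch_day`,
#'   `ase_id`.
#' @return a `ce_trace`.
#' @export
read_trace_tsv <- function(path, metadata = list()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("time", "signal") %in% names(df)))
    stop(path, " does not look like a trace TSV (need time, signal)", call. = FALSE)
  structure(list(time = df$time, signal = df$signal, metadata = metadata),
            class = "ce_trace")
}
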