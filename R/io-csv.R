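# CSV feature tables: comma-separated, '.' decimal, UTF-8, mandatory header,
# one designated label column. data.table does the parsing/writing.

#' Read a labeled feature table from CSV
#'
#' @param path CSV file with a header row and one integer label column.
#' @param label_col name of the label column (default `"label"`).
#' @return a [feature_table].
#' @export
read_csv_table <- function(path, label_col = "label") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          fill = FALSE)
  if (!label_col %in% names(dt))
    stopf("label column '%s' not found in %s", label_col, path)
  feats <- dt[setdiff(names(dt), label_col)]
  for (j in seq_along(feats)) {
    if (!is.numeric(feats[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(feats[[j]]))))[1]
      stopf("non-numeric feature cell at row %d, column '%s'",
            bad, names(feats)[j])
    }
  }
  feature_table(as.matrix(feats), as.integer(dt[[label_col]]), names(feats))
}

#' Write a feature table to CSV
#'
#' Values are written at full double precision (lossless to well beyond 12
#' significant digits on a round-trip).
#'
#' @param table a [feature_table].
#' @param path output path.
#' @param label_col name for the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
write_csv_table <- function(table, path, label_col = "label") {
  df <- as.data.frame(table$values)
  names(df) <- table$column_names
  df[[label_col]] <- table$labels
  data.table::fwrite(df, path, sep = ",", dec = ".")
  invisible(path)
}
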