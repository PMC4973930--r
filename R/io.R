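#' Read and write joint probability tables
#'
#' The on-disk format is delimited text: the first row holds the column
#' category values, the first column holds the row category values, and the
#' body holds cell probabilities.  Values are written with 17 significant
#' digits so a write/read round trip is bit-stable.
#'
#' Category labels must be numeric (the attributes are ordinal); supply
#' `row_values`/`col_values` to map non-numeric labels onto an explicit
#' ordinal index.  Printed margin rows/columns are not part of the format:
#' margins are always recomputed from cells.
#'
#' @param path file path.
#' @param sep field separator, `","` (CSV) or `"\t"` (TSV).
#' @param row_values,col_values optional explicit numeric category values
#'   overriding the file's labels.
#' @return `read_joint_table()` returns a validated `joint_table`;
#'   `write_joint_table()` returns `path` invisibly.
#' @export
read_joint_table <- function(path, sep = ",", row_values = NULL,
                             col_values = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    cbjf_abort("PARSE_ERROR", "%s: need a header line and at least one row", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1]))
    cbjf_abort("PARSE_ERROR", "%s: ragged row at line %d",
               path, which(widths != widths[1])[1])
  header <- fields[[1]][-1]
  body <- fields[-1]
  rlab <- vapply(body, `[`, "", 1L)
  cells <- do.call(rbind, lapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v))
      cbjf_abort("PARSE_ERROR", "%s: non-numeric cell value", path)
    v
  }))
  cv <- col_values %||% suppressWarnings(as.numeric(header))
  rv <- row_values %||% suppressWarnings(as.numeric(rlab))
  if (anyNA(cv) || anyNA(rv))
    cbjf_abort("NON_MONOTONE_VALUES",
      "%s: non-numeric category labels; supply row_values/col_values", path)
  joint_table(cells, rv, cv)
}

#' @param table a `joint_table` to write.
#' @rdname read_joint_table
#' @export
write_joint_table <- function(table, path, sep = ",") {
  table <- validate_joint(table)
  lines <- c(
    paste(c("value", fmt_num(table$col_values)), collapse = sep),
    vapply(seq_along(table$row_values), function(i) {
      paste(c(fmt_num(table$row_values[i]), fmt_num(table$cells[i, ])),
            collapse = sep)
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and write marginal distributions
#'
#' Margin files have two columns, `value` and `prob`, with a header line.
#'
#' @param path file path.
#' @param sep field separator.
#' @return `read_margin_vector()` returns a `margin_vector`;
#'   `write_margin_vector()` returns `path` invisibly.
#' @export
read_margin_vector <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) < 2L)
    cbjf_abort("PARSE_ERROR", "%s: expected columns value, prob", path)
  margin_vector(df[[2]], df[[1]])
}

#' @param margin a `margin_vector` to write.
#' @rdname read_margin_vector
#' @export
write_margin_vector <- function(margin, path, sep = ",") {
  margin <- as_margin(margin)
  lines <- c(paste(c("value", "prob"), collapse = sep),
             paste(fmt_num(margin$values), fmt_num(margin$probs), sep = sep))
  writeLines(lines, path)
  invisible(path)
}
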