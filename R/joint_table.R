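#' Joint probability table over two ordered attributes
#'
#' A `joint_table` stores an `m x n` matrix of cell probabilities together
#' with strictly increasing numeric category values for the rows (attribute
#' `X`) and columns (attribute `Y`).  Cells must be nonnegative and sum to 1
#' within a tolerance of `1e-9`; both attributes are assumed ordinal, which is
#' what makes cumulative distributions (and hence the empirical copula)
#' meaningful.
#'
#' @param cells numeric matrix of probabilities.
#' @param row_values strictly increasing numeric category values for rows
#'   (defaults to `1:m`).
#' @param col_values strictly increasing numeric category values for columns
#'   (defaults to `1:n`).
#' @return a validated object of class `joint_table` with elements `cells`,
#'   `row_values`, `col_values`.
#' @seealso [validate_joint()], [row_margins()], [cbjf_fit()]
#' @examples
#' a <- joint_table(matrix(c(0.5, 0, 0, 0.5), 2, 2))
#' row_margins(a)
#' @export
joint_table <- function(cells,
                        row_values = seq_len(nrow(cells)),
                        col_values = seq_len(ncol(cells))) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "double"
  x <- structure(
    list(cells = cells,
         row_values = as.numeric(row_values),
         col_values = as.numeric(col_values)),
    class = "joint_table"
  )
  validate_joint(x)
}

#' Validate a joint probability table
#'
#' Checks the `joint_table` invariants: nonnegative cells, total mass 1
#' within `1e-9`, and strictly increasing category values.  Raises a classed
#' error naming the offending entry otherwise.
#'
#' @param table a `joint_table` (or a bare list with the same fields).
#' @param tol tolerance on the total probability mass.
#' @return `table`, unchanged, if all invariants hold.
#' @section Errors: `NEGATIVE_CELL`, `SUM_NOT_ONE` (reports the observed sum),
#'   `NON_MONOTONE_VALUES`, `DIMENSION_MISMATCH`.
#' @export
validate_joint <- function(table, tol = 1e-9) {
  cells <- table$cells
  if (!is.matrix(cells) || nrow(cells) < 1L || ncol(cells) < 1L)
    cbjf_abort("DIMENSION_MISMATCH", "cells must be a matrix with m >= 1, n >= 1")
  if (length(table$row_values) != nrow(cells) ||
      length(table$col_values) != ncol(cells))
    cbjf_abort("DIMENSION_MISMATCH",
               "category values do not match table dimensions (%d x %d)",
               nrow(cells), ncol(cells))
  neg <- which(cells < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    cbjf_abort("NEGATIVE_CELL", "negative probability at cell (%d, %d): %g",
               neg[1, 1], neg[1, 2], cells[neg[1, 1], neg[1, 2]])
  s <- sum(cells)
  if (abs(s - 1) > tol)
    cbjf_abort("SUM_NOT_ONE", "cell probabilities sum to %.12g, not 1", s)
  if (any(diff(table$row_values) <= 0))
    cbjf_abort("NON_MONOTONE_VALUES",
               "row_values not strictly increasing at index %d",
               which(diff(table$row_values) <= 0)[1] + 1L)
  if (any(diff(table$col_values) <= 0))
    cbjf_abort("NON_MONOTONE_VALUES",
               "col_values not strictly increasing at index %d",
               which(diff(table$col_values) <= 0)[1] + 1L)
  table
}

#' @export
print.joint_table <- function(x, digits = 4, ...) {
  cat(sprintf("joint_table: %d x %d, total mass %.9f\n",
              nrow(x$cells), ncol(x$cells), sum(x$cells)))
  m <- round(x$cells, digits)
  dimnames(m) <- list(format(x$row_values), format(x$col_values))
  print(m)
  invisible(x)
}

#' Marginal probability vector over ordered categories
#'
#' @param probs nonnegative probabilities summing to 1 within `1e-9`.
#' @param values strictly increasing numeric category values.
#' @return an object of class `margin_vector` with elements `probs`, `values`.
#' @export
margin_vector <- function(probs, values = seq_along(probs)) {
  probs <- as.numeric(probs)
  values <- as.numeric(values)
  if (length(values) != length(probs))
    cbjf_abort("DIMENSION_MISMATCH", "values and probs differ in length")
  if (any(probs < 0))
    cbjf_abort("NEGATIVE_CELL", "negative probability at index %d",
               which(probs < 0)[1])
  if (abs(sum(probs) - 1) > 1e-9)
    cbjf_abort("SUM_NOT_ONE", "margin probabilities sum to %.12g, not 1",
               sum(probs))
  if (any(diff(values) <= 0))
    cbjf_abort("NON_MONOTONE_VALUES",
               "values not strictly increasing at index %d",
               which(diff(values) <= 0)[1] + 1L)
  structure(list(probs = probs, values = values), class = "margin_vector")
}

#' @export
print.margin_vector <- function(x, digits = 4, ...) {
  cat("margin_vector:\n")
  p <- round(x$probs, digits)
  names(p) <- format(x$values)
  print(p)
  invisible(x)
}

## Accept either a margin_vector or a bare probability vector.
#' @keywords internal
as_margin <- function(x, values = NULL) {
  if (inherits(x, "margin_vector")) return(x)
  margin_vector(x, values %||% seq_along(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row and column margins of a joint table
#'
#' The margins are always recomputed from the cells (never read from a file's
#' printed margin row/column, which may be inconsistent with the cells).
#'
#' @param table a `joint_table`.
#' @return a `margin_vector` carrying the axis' category values.
#' @export
row_margins <- function(table) {
  table <- validate_joint(table)
  margin_vector(rowSums(table$cells), table$row_values)
}

#' @rdname row_margins
#' @export
col_margins <- function(table) {
  table <- validate_joint(table)
  margin_vector(colSums(table$cells), table$col_values)
}

#' The built-in small worked example
#'
#' A 7 x 5 reference joint table with a staircase support, together with
#' target margins that differ from the reference margins on both axes.  This
#' problem is small enough to follow every algorithm by hand and exercises the
#' interesting cases: zero cells, margins shifted up and down, and diffusion
#' of probability into cells that are empty in the reference.
#'
#' @return a list with elements `a` (`joint_table`), `r` and `c`
#'   (`margin_vector` targets for rows and columns).
#' @examples
#' prob <- example_joint_problem()
#' b <- cbjf_fit(prob$a, prob$r, prob$c)
#' round_half_up(b$cells, 3)
#' @export
example_joint_problem <- function() {
  cells <- matrix(c(
    0.04, 0,    0,    0,    0,
    0.08, 0.04, 0,    0,    0,
    0,    0.12, 0.08, 0,    0,
    0,    0,    0.16, 0,    0.04,
    0,    0,    0.04, 0.20, 0,
    0,    0,    0.04, 0.04, 0.04,
    0,    0,    0.04, 0.04, 0
  ), nrow = 7, byrow = TRUE)
  list(
    a = joint_table(cells),
    r = margin_vector(c(0.07, 0.13, 0.15, 0.25, 0.27, 0.07, 0.06)),
    c = margin_vector(c(0.16, 0.17, 0.30, 0.25, 0.12))
  )
}
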