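#' Fitting error of a table against target margins
#'
#' The maximum absolute row-margin deviation plus the maximum absolute
#' column-margin deviation,
#' `max_i |b_{i+} - r_i| + max_j |b_{+j} - c_j|`.
#' This is the convergence criterion used by the iterative fitters and the
#' margin-exactness yardstick for the copula fitter.
#'
#' @param table a `joint_table`.
#' @param r,c target margins (`margin_vector` or probability vector).
#' @return a nonnegative scalar.
#' @export
fitting_error <- function(table, r, c) {
  table <- validate_joint(table)
  r <- as_margin(r); c <- as_margin(c)
  if (length(r$probs) != nrow(table$cells) ||
      length(c$probs) != ncol(table$cells))
    cbjf_abort("DIMENSION_MISMATCH", "margin lengths do not match table")
  max(abs(rowSums(table$cells) - r$probs)) +
    max(abs(colSums(table$cells) - c$probs))
}

#' Relative entropy (discrimination information) between two tables
#'
#' `RE(b, a) = sum_ij b_ij log(b_ij / a_ij)` with the convention
#' `0 log(0/x) = 0`.  Returns `Inf` when some `b_ij > 0` has `a_ij = 0`
#' (mass created where the reference assigns none).  By Gibbs' inequality
#' `RE >= 0`, with equality iff `b == a`.
#'
#' @param b,a `joint_table`s of the same shape.
#' @return a nonnegative scalar, possibly `Inf`.
#' @export
relative_entropy <- function(b, a) {
  b <- validate_joint(b); a <- validate_joint(a)
  if (!all(dim(b$cells) == dim(a$cells)))
    cbjf_abort("DIMENSION_MISMATCH", "tables differ in shape")
  bb <- b$cells; aa <- a$cells
  if (any(bb > 0 & aa == 0)) return(Inf)
  pos <- bb > 0
  sum(bb[pos] * log(bb[pos] / aa[pos]))
}

#' Marginal variation between two pairs of margins
#'
#' The sum over axes of the total variation distance
#' `delta(P, Q) = 0.5 * sum |P - Q|` between reference and target margins.
#' This is the scalar knob used to quantify "how much the margins changed"
#' in the benchmark sweeps; its range is `[0, 2]`.
#'
#' @param r_ref,c_ref reference row/column margins.
#' @param r_tgt,c_tgt target row/column margins.
#' @return a nonnegative scalar in `[0, 2]`.
#' @export
marginal_variation <- function(r_ref, c_ref, r_tgt, c_tgt) {
  r_ref <- as_margin(r_ref); c_ref <- as_margin(c_ref)
  r_tgt <- as_margin(r_tgt); c_tgt <- as_margin(c_tgt)
  if (length(r_ref$probs) != length(r_tgt$probs) ||
      length(c_ref$probs) != length(c_tgt$probs))
    cbjf_abort("DIMENSION_MISMATCH", "margin lengths differ per axis")
  0.5 * sum(abs(r_ref$probs - r_tgt$probs)) +
    0.5 * sum(abs(c_ref$probs - c_tgt$probs))
}
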