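#' Copula-based resampling of micro-records
#'
#' Turns a set of reference micro-records (e.g. PUMS survey entries) plus
#' target margins into a weighted resampling pool.  Each record carries two
#' binned ordinal attributes `x`, `y` and arbitrary extra attributes that are
#' passed through untouched.  A record is treated as a cell of the empirical
#' reference partition holding mass `1/N`; that mass is distributed over the
#' overlapping target cells in proportion to the overlapping area, exactly as
#' in [cbjf_distribute()] applied at record granularity.  Each emitted copy
#' takes the target cell's category values for `(x, y)`, keeps the record's
#' extra attributes, and receives selection probability
#' `w = overlap_fraction / N`; weights sum to 1 over the pool.
#'
#' Aggregating the pool weights by `(x, y)` reproduces
#' `cbjf_distribute(empirical joint of P, r, c)` exactly — records only add
#' the ability to carry extra attributes into the synthetic population.
#'
#' @param records data frame with numeric columns `x` and `y`; any further
#'   columns are carried through.
#' @param x_breaks,y_breaks bin edges of the reference grid (length
#'   `m+1` / `n+1`, strictly increasing).  Records must fall inside
#'   `[first, last]`; the bins are left-open except the first.
#' @param r,c target margins; their `values` become the emitted `(x, y)`
#'   attribute values.
#' @return a data frame (`weighted_set`): columns `x`, `y`, the carried
#'   attributes, source row `src`, and weight `w`.
#' @export
cbjf_resample <- function(records, x_breaks, y_breaks, r, c) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    cbjf_abort("EMPTY_SET", "records must be a nonempty data frame")
  if (!all(c("x", "y") %in% names(records)))
    cbjf_abort("PARSE_ERROR", "records need numeric columns x and y")
  r <- as_margin(r); c <- as_margin(c)
  N <- nrow(records)
  ix <- bin_index(records$x, x_breaks, "x")
  iy <- bin_index(records$y, y_breaks, "y")
  m <- length(x_breaks) - 1L; n <- length(y_breaks) - 1L
  ## empirical reference partition: each cell's mass = record count / N
  rowm <- tabulate(ix, m) / N
  colm <- tabulate(iy, n) / N
  u <- pmin(c(0, cumsum(rowm)), 1); u[m + 1L] <- 1
  v <- pmin(c(0, cumsum(colm)), 1); v[n + 1L] <- 1
  ut <- pmin(c(0, cumsum(r$probs)), 1); ut[length(ut)] <- 1
  vt <- pmin(c(0, cumsum(c$probs)), 1); vt[length(vt)] <- 1
  zcols <- setdiff(names(records), c("x", "y"))
  out <- vector("list", N)
  for (k in seq_len(N)) {
    fx <- interval_overlaps(u[ix[k]], u[ix[k] + 1L], ut)
    fy <- interval_overlaps(v[iy[k]], v[iy[k] + 1L], vt)
    grid <- expand.grid(s = seq_along(fx$idx), t = seq_along(fy$idx))
    copies <- data.frame(
      x = r$values[fx$idx[grid$s]],
      y = c$values[fy$idx[grid$t]],
      src = k,
      w = fx$frac[grid$s] * fy$frac[grid$t] / N
    )
    out[[k]] <- copies
  }
  pool <- do.call(rbind, out)
  if (length(zcols))
    pool <- cbind(pool[c("x", "y")], records[pool$src, zcols, drop = FALSE],
                  pool[c("src", "w")])
  rownames(pool) <- NULL
  class(pool) <- c("weighted_set", "data.frame")
  pool
}

#' @keywords internal
bin_index <- function(x, breaks, axis) {
  if (any(diff(breaks) <= 0))
    cbjf_abort("NON_MONOTONE_VALUES", "%s_breaks must be strictly increasing", axis)
  if (any(x < breaks[1] | x > breaks[length(breaks)]))
    cbjf_abort("UNBINNABLE_RECORD", "record %s value outside bin edges", axis)
  i <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  i
}

#' Aggregate pool weights into a joint table
#'
#' Sums the selection probabilities of a [cbjf_resample()] pool by `(x, y)`
#' cell, yielding the fitted target joint table the pool realizes.
#'
#' @param pool a `weighted_set` data frame.
#' @param r,c the target margins that were used to build the pool (their
#'   `values` define the cell grid).
#' @return a `joint_table`.
#' @export
aggregate_weights <- function(pool, r, c) {
  r <- as_margin(r); c <- as_margin(c)
  i <- match(pool$x, r$values); j <- match(pool$y, c$values)
  if (anyNA(i) || anyNA(j))
    cbjf_abort("DIMENSION_MISMATCH", "pool (x, y) values not on the target grid")
  b <- matrix(0, length(r$probs), length(c$probs))
  for (k in seq_len(nrow(pool)))
    b[i[k], j[k]] <- b[i[k], j[k]] + pool$w[k]
  joint_table(b / sum(b), r$values, c$values)
}

#' Quantile transform of micro-records to continuous target margins
#'
#' For continuous attributes, the fitted records are obtained directly: the
#' transformed pair `(qx(F_X(x)), qy(F_Y(y)))` shares the copula of `(x, y)`
#' while taking the target margins.  The empirical CDF uses the max-rank
#' convention `u_k = #\{l : x_l <= x_k\} / N`, so `u` lies in `(0, 1]` and
#' tied records receive identical transforms; quantile functions therefore
#' need only be defined on `(0, 1]`.  Sort order (and hence the dependence
#' ranking) is preserved.
#'
#' @param records data frame with numeric columns `x`, `y` and carried extras.
#' @param target_qx,target_qy quantile functions defined on `(0, 1]`.
#' @return the transformed data frame, same rows and columns.
#' @export
cbjf_continuous <- function(records, target_qx, target_qy) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    cbjf_abort("EMPTY_SET", "records must be a nonempty data frame")
  N <- nrow(records)
  ## max rank among ties: #\{l : value_l <= value_k\}
  rx <- rank(records$x, ties.method = "max")
  ry <- rank(records$y, ties.method = "max")
  xt <- target_qx(rx / N)
  yt <- target_qy(ry / N)
  if (any(!is.finite(xt)) || any(!is.finite(yt)))
    cbjf_abort("NONFINITE_QUANTILE", "quantile function returned non-finite value")
  out <- records
  out$x <- xt; out$y <- yt
  out
}

#' Draw a synthetic population from a weighted pool
#'
#' I.i.d. categorical draws of pool rows by selection probability, by
#' inverse-CDF lookup on the cumulative weights.  The seed is a required
#' argument; no global RNG state is consumed.
#'
#' @param pool a `weighted_set` (weights in column `w`, summing to 1).
#' @param size number of agents to draw.
#' @param seed integer RNG seed.
#' @return a data frame of `size` drawn records (without the `w` column).
#' @export
draw_population <- function(pool, size, seed) {
  if (!is.data.frame(pool) || nrow(pool) == 0L)
    cbjf_abort("EMPTY_SET", "pool is empty")
  if (abs(sum(pool$w) - 1) > 1e-9)
    cbjf_abort("SUM_NOT_ONE", "pool weights sum to %.12g", sum(pool$w))
  cw <- cumsum(pool$w)
  cw[length(cw)] <- 1
  idx <- with_seed(seed, findInterval(stats::runif(size), cw) + 1L)
  out <- pool[idx, setdiff(names(pool), "w"), drop = FALSE]
  rownames(out) <- NULL
  out
}
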