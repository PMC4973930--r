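#' Cumulative grid (empirical copula support) of a joint table
#'
#' Computes the joint CDF `A` of a table on the grid of marginal CDF
#' breakpoints: `A[i, j] = P[X <= x_i, Y <= y_j]` (stored with a zero-padded
#' first row/column, so `A` is `(m+1) x (n+1)`), together with the marginal
#' CDF breakpoints `u_0..u_m` and `v_0..v_n`.  These are exactly the points
#' at which the copula of a discrete pair is uniquely determined; between
#' them the copula is defined by bilinear interpolation ([copula_eval()]).
#'
#' The trailing breakpoints are pinned to 1 exactly so that the interpolated
#' copula has exactly uniform margins.
#'
#' @param a a `joint_table`.
#' @return an object of class `cumulative_grid` with elements `A`
#'   (`(m+1) x (n+1)` joint CDF values), `u`, `v` (marginal CDF breakpoints
#'   including the leading 0).
#' @export
cumulative_grid <- function(a) {
  a <- validate_joint(a)
  m <- nrow(a$cells); n <- ncol(a$cells)
  A <- matrix(0, m + 1L, n + 1L)
  A[-1L, -1L] <- t(apply(apply(a$cells, 2L, cumsum), 1L, cumsum))
  u <- pmin(c(0, cumsum(rowSums(a$cells))), 1)   # cumsum may overshoot by 1 ulp
  v <- pmin(c(0, cumsum(colSums(a$cells))), 1)
  u[m + 1L] <- 1; v[n + 1L] <- 1
  A[m + 1L, ] <- v; A[, n + 1L] <- u   # exact uniform-margin boundary
  structure(list(A = A, u = u, v = v, m = m, n = n),
            class = "cumulative_grid")
}

#' @export
print.cumulative_grid <- function(x, ...) {
  cat(sprintf("cumulative_grid on a %d x %d table\n", x$m, x$n))
  cat("u:", format(round(x$u, 4)), "\n")
  cat("v:", format(round(x$v, 4)), "\n")
  invisible(x)
}

## Locate probe points in a breakpoint vector under the half-open convention
## [g_i, g_{i+1}) with the final cell closed at 1; zero-width intervals
## (empty marginal bins) are skipped, so the cell is unique.  Returns the
## interval index i (interval [g_i, g_{i+1}], 1-based over intervals) and the
## local coordinate s in [0, 1], with s = 0 on a zero-width interval.
#' @keywords internal
locate_1d <- function(grid, q) {
  i <- findInterval(q, grid)          # ties resolve to the last equal breakpoint
  i[i >= length(grid)] <- length(grid) - 1L
  ## at q = 1 (or trailing empty bins) step back to the last positive-width cell
  hi <- which(grid[i + 1L] <= grid[i] & i > 1L)
  while (length(hi)) {
    i[hi] <- i[hi] - 1L
    hi <- which(grid[i + 1L] <= grid[i] & i > 1L)
  }
  w <- grid[i + 1L] - grid[i]
  s <- ifelse(w > 0, (q - grid[i]) / w, 0)
  list(i = i, s = pmin(pmax(s, 0), 1))
}

#' Locate a point of the unit square in the copula grid
#'
#' Finds the unique grid cell containing `(u, v)` under the half-open
#' convention (cells `[u_i, u_{i+1}) x [v_j, v_{j+1})`, with the final cell
#' closed at 1 and zero-width cells skipped) and the local bilinear
#' coordinates `s = (u - u_i)/(u_{i+1} - u_i)`, `t` likewise (`0` on a
#' zero-width cell).
#'
#' @param grid a [cumulative_grid()].
#' @param u,v coordinates in `[0, 1]` (vectorized).
#' @return a list with integer vectors `i`, `j` (1-based cell indices) and
#'   numeric vectors `s`, `t` in `[0, 1]`.
#' @export
copula_locate <- function(grid, u, v) {
  if (any(u < 0 | u > 1 | v < 0 | v > 1))
    cbjf_abort("OUT_OF_RANGE", "copula arguments must lie in [0, 1]")
  lu <- locate_1d(grid$u, u)
  lv <- locate_1d(grid$v, v)
  list(i = lu$i, j = lv$i, s = lu$s, t = lv$s)
}

#' Evaluate the bilinearly interpolated empirical copula
#'
#' `C(u, v)` interpolates the joint CDF values `A` bilinearly within the grid
#' cell located by [copula_locate()]:
#' `C = (1-s)(1-t) A[i,j] + (1-s) t A[i,j+1] + s (1-t) A[i+1,j] + s t A[i+1,j+1]`.
#' The result is continuous on the unit square, has exactly uniform margins
#' (`C(u, 1) = u`, `C(1, v) = v`, `C(u, 0) = C(0, v) = 0`), is nondecreasing
#' in each argument, and satisfies the rectangle inequality — i.e. it is a
#' copula carrying the dependence structure of the reference table.
#'
#' @inheritParams copula_locate
#' @return numeric vector of copula values.
#' @export
copula_eval <- function(grid, u, v) {
  loc <- copula_locate(grid, u, v)
  A <- grid$A
  i <- loc$i; j <- loc$j; s <- loc$s; t <- loc$t
  (1 - s) * (1 - t) * A[cbind(i, j)] +
    (1 - s) * t * A[cbind(i, j + 1L)] +
    s * (1 - t) * A[cbind(i + 1L, j)] +
    s * t * A[cbind(i + 1L, j + 1L)]
}

#' Copula-based joint fitting (collection view)
#'
#' Builds the bilinear empirical copula of the reference table `a`, evaluates
#' it at the cumulative target margins, and takes second differences:
#' `b_kl = C(u~_k, v~_l) - C(u~_{k-1}, v~_l) - C(u~_k, v~_{l-1}) + C(u~_{k-1}, v~_{l-1})`.
#' The output matches the target margins exactly (to float error, because the
#' copula's margins are exactly uniform and the sums telescope), every cell
#' is nonnegative (rectangle inequality), and when the target margins equal
#' the reference margins the output is the reference table itself.
#'
#' Unlike iterative proportional fitting, mass can diffuse into cells that
#' are zero in the reference when the target margins call for it, and no
#' iteration or convergence question arises.
#'
#' @param a reference `joint_table`.
#' @param r,c target margins; their lengths set the output dimensions (for the
#'   usual fitting problem they match the reference dimensions).
#' @return the fitted `joint_table`, with category values taken from the
#'   target margins.
#' @examples
#' prob <- example_joint_problem()
#' b <- cbjf_fit(prob$a, prob$r, prob$c)
#' fitting_error(b, prob$r, prob$c)   # ~1e-16: margins are exact
#' @export
cbjf_fit <- function(a, r, c) {
  a <- validate_joint(a)
  if (!inherits(r, "margin_vector"))
    r <- margin_vector(r, if (length(r) == nrow(a$cells)) a$row_values
                          else seq_along(r))
  if (!inherits(c, "margin_vector"))
    c <- margin_vector(c, if (length(c) == ncol(a$cells)) a$col_values
                          else seq_along(c))
  grid <- cumulative_grid(a)
  ut <- pmin(c(0, cumsum(r$probs)), 1); ut[length(ut)] <- 1
  vt <- pmin(c(0, cumsum(c$probs)), 1); vt[length(vt)] <- 1
  ## evaluate C once at all (m~+1) x (n~+1) breakpoints, then difference:
  ## the telescoping guarantees exact margins and total mass 1
  B <- outer(pmin(ut, 1), pmin(vt, 1),
             function(uu, vv) copula_eval(grid, uu, vv))
  b <- B[-1L, -1L, drop = FALSE] - B[-nrow(B), -1L, drop = FALSE] -
    B[-1L, -ncol(B), drop = FALSE] + B[-nrow(B), -ncol(B), drop = FALSE]
  b[b < 0] <- 0                        # clip float negatives (~ -1e-17)
  joint_table(b / sum(b), r$values, c$values)
}

#' Copula-based joint fitting (sparse distribution view)
#'
#' The same fit as [cbjf_fit()], computed the other way around: the reference
#' margins partition the unit square into cells `G_ij` carrying mass `a_ij`,
#' the target margins overlay a second partition, and each nonzero `a_ij` is
#' distributed over the overlapping target cells in proportion to the
#' overlapping area (which factorizes into per-axis interval overlaps).  Only
#' nonzero reference cells are visited, so run time and memory scale with the
#' support size — the form that generalizes to high-dimensional sparse
#' tables.  The result equals [cbjf_fit()] up to float round-off.
#'
#' @param a reference table: either a `joint_table` or a data frame of sparse
#'   triples with columns `i`, `j`, `mass` (1-based indices; duplicate
#'   coordinates are summed).
#' @param r,c target margins.
#' @param sparse if `TRUE` return sparse triples (a data frame `i, j, mass`),
#'   otherwise a dense `joint_table`.
#' @return a `joint_table` or sparse triple data frame.
#' @export
cbjf_distribute <- function(a, r, c, sparse = FALSE) {
  r <- as_margin(r); c <- as_margin(c)
  if (is.data.frame(a)) {
    trip <- sparse_triples_collapse(a)
    m <- max(trip$i); n <- max(trip$j)
    if (abs(sum(trip$mass) - 1) > 1e-9)
      cbjf_abort("SUM_NOT_ONE", "sparse masses sum to %.12g", sum(trip$mass))
    rowm <- numeric(m); colm <- numeric(n)
    rowm[sort(unique(trip$i))] <-
      vapply(split(trip$mass, trip$i), sum, 0)
    colm[sort(unique(trip$j))] <-
      vapply(split(trip$mass, trip$j), sum, 0)
  } else {
    a <- validate_joint(a)
    nz <- which(a$cells > 0, arr.ind = TRUE)
    trip <- data.frame(i = nz[, 1], j = nz[, 2],
                       mass = a$cells[nz])
    rowm <- rowSums(a$cells); colm <- colSums(a$cells)
    m <- nrow(a$cells); n <- ncol(a$cells)
  }
  u <- pmin(c(0, cumsum(rowm)), 1); u[m + 1L] <- 1
  v <- pmin(c(0, cumsum(colm)), 1); v[n + 1L] <- 1
  ut <- pmin(c(0, cumsum(r$probs)), 1); ut[length(ut)] <- 1
  vt <- pmin(c(0, cumsum(c$probs)), 1); vt[length(vt)] <- 1
  if (any(trip$mass > 0 & (u[trip$i + 1L] <= u[trip$i] |
                           v[trip$j + 1L] <= v[trip$j])))
    cbjf_abort("INTERNAL", "positive mass in a zero-area reference cell")
  mt <- length(r$probs); nt <- length(c$probs)
  b <- matrix(0, mt, nt)
  for (k in seq_len(nrow(trip))) {
    i <- trip$i[k]; j <- trip$j[k]
    fx <- interval_overlaps(u[i], u[i + 1L], ut)
    fy <- interval_overlaps(v[j], v[j + 1L], vt)
    b[fx$idx, fy$idx] <- b[fx$idx, fy$idx] +
      trip$mass[k] * outer(fx$frac, fy$frac)
  }
  if (sparse) {
    nzb <- which(b > 0, arr.ind = TRUE)
    data.frame(i = nzb[, 1], j = nzb[, 2], mass = b[nzb])
  } else {
    joint_table(b / sum(b), r$values, c$values)
  }
}

## Fractions of the interval [lo, hi] covered by each cell of the partition
## `brk` (breakpoints).  Returns only cells with positive overlap.
#' @keywords internal
interval_overlaps <- function(lo, hi, brk) {
  nI <- length(brk) - 1L
  i0 <- max(1L, findInterval(lo, brk, rightmost.closed = TRUE))
  i1 <- max(1L, findInterval(hi, brk, left.open = TRUE, rightmost.closed = TRUE))
  i1 <- min(i1, nI)
  idx <- i0:i1
  ov <- pmin(hi, brk[idx + 1L]) - pmax(lo, brk[idx])
  keep <- ov > 0
  list(idx = idx[keep], frac = ov[keep] / (hi - lo))
}

## Sum duplicate coordinates and sort triples lexicographically.
#' @keywords internal
sparse_triples_collapse <- function(df) {
  if (!all(c("i", "j", "mass") %in% names(df)))
    cbjf_abort("PARSE_ERROR", "sparse triples need columns i, j, mass")
  agg <- stats::aggregate(mass ~ i + j, data = df, FUN = sum)
  agg[order(agg$i, agg$j), , drop = FALSE]
}
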