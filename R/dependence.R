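#' Exact dependence measures on a joint probability table
#'
#' All three correlation measures are computed exactly from the table's
#' masses and category values — no sampling.
#'
#' * `pearson_from_table()`: product-moment correlation
#'   `Cov(X, Y) / sqrt(Var X Var Y)` with moments
#'   `E[XY] = sum_ij b_ij x_i y_j` etc.
#' * `spearman_from_table()`: the Pearson correlation of the CDF-transformed
#'   pair `(F_X(X), F_Y(Y))`, where `F` is evaluated *at* the atom
#'   (`u_i = P[X <= x_i]`).  Set `midrank = TRUE` for the mid-rank
#'   convention `u_i - a_{i+}/2` used by some discrete-Spearman definitions.
#' * `kendall_from_table()`: `E[sign((X1 - X2)(Y1 - Y2))]` over two
#'   independent draws — concordance minus discordance probability, with no
#'   tie normalization (ties contribute 0, as in tau-a).
#'
#' @param b a `joint_table`.
#' @return a scalar in `[-1, 1]`.
#' @export
pearson_from_table <- function(b) {
  b <- validate_joint(b)
  x <- b$row_values; y <- b$col_values
  px <- rowSums(b$cells); py <- colSums(b$cells)
  ex <- sum(px * x); ey <- sum(py * y)
  vx <- sum(px * (x - ex)^2); vy <- sum(py * (y - ey)^2)
  if (vx <= 0 || vy <= 0)
    cbjf_abort("ZERO_VARIANCE", "a margin is degenerate (zero variance)")
  exy <- sum(b$cells * outer(x, y))
  (exy - ex * ey) / sqrt(vx * vy)
}

#' @param midrank use the mid-rank CDF convention for the transform.
#' @rdname pearson_from_table
#' @export
spearman_from_table <- function(b, midrank = FALSE) {
  b <- validate_joint(b)
  px <- rowSums(b$cells); py <- colSums(b$cells)
  u <- cumsum(px); v <- cumsum(py)
  if (midrank) { u <- u - px / 2; v <- v - py / 2 }
  pearson_from_table(joint_table(b$cells, rank_safe(u), rank_safe(v)))
}

## CDF values can tie when margin bins are empty; nudge into a strictly
## increasing sequence without changing the transform on nonempty bins.
#' @keywords internal
rank_safe <- function(u) {
  eps <- cumsum(c(0, diff(u) <= 0)) * 1e-12
  u + eps
}

#' @rdname pearson_from_table
#' @export
kendall_from_table <- function(b) {
  b <- validate_joint(b)
  B <- b$cells
  m <- nrow(B); n <- ncol(B)
  ## sign matrices of value differences; values strictly increasing, so
  ## sign(x_i - x_k) = sign(i - k)
  Sx <- sign(outer(seq_len(m), seq_len(m), `-`))   # Sx[i, k] = sign(x_i - x_k)
  Sy <- sign(outer(seq_len(n), seq_len(n), `-`))
  ## tau = sum_{ij,kl} b_ij b_kl sign(x_i - x_k) sign(y_j - y_l)
  sum(B * (Sx %*% B %*% t(Sy)))
}

#' Draw sample points from a joint table
#'
#' I.i.d. cell draws by probability mass, with the cell's category values as
#' coordinates.  With `jitter = TRUE` a uniform within-bin offset is added
#' (bin widths from consecutive category values), which restores
#' continuous-like behavior for tables that discretize a continuous joint —
#' appropriate for grid-based statistics such as the MIC.  Keep
#' `jitter = FALSE` for genuinely ordinal tables.
#'
#' @param b a `joint_table`.
#' @param n number of points.
#' @param seed integer RNG seed (required; no global RNG state is used).
#' @param jitter add uniform within-bin offsets.
#' @return a two-column matrix of `(x, y)` points.
#' @export
sample_from_table <- function(b, n, seed, jitter = FALSE) {
  b <- validate_joint(b)
  p <- as.vector(b$cells)
  cw <- cumsum(p) / sum(p)
  cw[length(cw)] <- 1
  m <- nrow(b$cells)
  with_seed(seed, {
    k <- findInterval(stats::runif(n), cw) + 1L
    i <- (k - 1L) %% m + 1L
    j <- (k - 1L) %/% m + 1L
    x <- b$row_values[i]; y <- b$col_values[j]
    if (jitter) {
      wx <- bin_widths(b$row_values); wy <- bin_widths(b$col_values)
      x <- x + stats::runif(n, -0.5, 0.5) * wx[i]
      y <- y + stats::runif(n, -0.5, 0.5) * wy[j]
    }
    cbind(x = x, y = y)
  })
}

## Bin width per category value (centers): adjacent-midpoint widths, which
## reduce to the spacing for an equally spaced grid.
#' @keywords internal
bin_widths <- function(v) {
  if (length(v) == 1L) return(1)
  d <- diff(v)
  if (length(d) == 1L) return(rep(d, 2L))
  c(d[1], (d[-length(d)] + d[-1]) / 2, d[length(d)])
}

#' Maximal information coefficient (MIC)
#'
#' The MINE statistic of Reshef et al.: the maximum, over all grids with at
#' most `B(n) = n^alpha` cells, of the normalized mutual information of the
#' induced discretization, computed with the standard approximation
#' (equipartition one axis, dynamic-programming optimization of the other,
#' clump merging bounded by `c` times the column budget; both orientations).
#' MIC lies in `[0, 1]`: near 0 for independent data, near 1 for a noiseless
#' functional relationship of either axis on the other.
#'
#' @param x numeric vector, or a two-column matrix of points.
#' @param y numeric vector (ignored when `x` is a matrix).
#' @param alpha grid-size exponent, `B(n) = n^alpha` (default 0.6).
#' @param c clump factor (default 15).
#' @return the MIC statistic in `[0, 1]`.
#' @export
mic <- function(x, y = NULL, alpha = 0.6, c = 15) {
  if (is.matrix(x)) { y <- x[, 2]; x <- x[, 1] }
  if (length(x) != length(y) || length(x) < 4L)
    cbjf_abort("DEGENERATE_INPUT", "need paired samples, at least 4 points")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    cbjf_abort("DEGENERATE_INPUT", "need at least 2 distinct values per axis")
  mine_mic(as.numeric(x), as.numeric(y), alpha, as.integer(c))
}

#' Dependence-preservation report for a fitted table
#'
#' Computes Pearson, Spearman, Kendall and MIC for a fitted table and the
#' absolute deviation of each measure from a reference table's value — the
#' quantities used to judge how well a fitter preserved the reference
#' dependence structure.  The MIC is sample-based: `mic_samples` points are
#' drawn from each table under the *same* seed (common random numbers, which
#' makes the MIC deviation far less noisy than two independent estimates).
#'
#' @param b fitted `joint_table`.
#' @param ref reference `joint_table` with the same category values.
#' @param mic_samples sample points for the MIC (default 10000).
#' @param seed RNG seed for the MIC sampling.
#' @param jitter within-bin jitter for MIC sampling (default `TRUE`:
#'   discretized-continuous tables).
#' @return an object of class `dependence_report`: a list with `measures`
#'   (named numeric: pearson, spearman, kendall, mic), `reference`,
#'   `deviations`, `mic_samples`, `seed`.
#' @export
dependence_report <- function(b, ref, mic_samples = 10000L, seed = 1L,
                              jitter = TRUE) {
  b <- validate_joint(b); ref <- validate_joint(ref)
  if (!isTRUE(all.equal(b$row_values, ref$row_values)) ||
      !isTRUE(all.equal(b$col_values, ref$col_values)))
    cbjf_abort("DIMENSION_MISMATCH", "tables must share category values")
  meas <- function(t) c(
    pearson = pearson_from_table(t),
    spearman = spearman_from_table(t),
    kendall = kendall_from_table(t),
    mic = mic(sample_from_table(t, mic_samples, seed = seed, jitter = jitter))
  )
  mb <- meas(b); mr <- meas(ref)
  structure(list(measures = mb, reference = mr,
                 deviations = abs(mr - mb),
                 mic_samples = as.integer(mic_samples),
                 seed = as.integer(seed)),
            class = "dependence_report")
}

#' @export
print.dependence_report <- function(x, ...) {
  tab <- rbind(observed = x$measures, reference = x$reference,
               abs_deviation = x$deviations)
  print(round(tab, 3))
  invisible(x)
}
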