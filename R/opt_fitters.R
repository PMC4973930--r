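#' Cell weights and big-M for the optimization baselines
#'
#' Both optimization baselines penalize deviations from the reference cell
#' `a_ij` with weight `w_ij = 1/a_ij` for nonzero cells and a large constant
#' `M` for zero cells (discouraging, but not forbidding, mass in structural
#' zeros).  The default ties `M` to the data scale,
#' `M = 1e6 * max(1/a_ij over nonzero cells)`, keeping the conditioning sane;
#' beyond a threshold the solution is insensitive to `M`.
#'
#' @param a reference `joint_table`.
#' @param big_M optional override; must exceed `max(1/a_ij)` over nonzero
#'   cells.
#' @return list with the weight matrix `w` and the `big_M` used.
#' @export
fit_problem_weights <- function(a, big_M = NULL) {
  a <- validate_joint(a)
  inv <- 1 / a$cells[a$cells > 0]
  if (is.null(big_M)) big_M <- 1e6 * max(inv)
  if (big_M <= max(inv))
    cbjf_abort("INVALID_STRENGTH",
               "big_M must exceed max(1/a_ij) over nonzero cells (%g)", max(inv))
  w <- ifelse(a$cells > 0, 1 / pmax(a$cells, .Machine$double.xmin), big_M)
  list(w = w, big_M = big_M)
}

#' Weighted least-squares joint fitting (QP baseline)
#'
#' Minimizes `sum_ij w_ij (b_ij - a_ij)^2` subject to exact target margins
#' and `b_ij >= 0`, with weights from [fit_problem_weights()].  The problem
#' is a strictly convex separable QP over the transportation polytope; it is
#' solved by a primal active-set Newton method exploiting that structure: on
#' the current free set the stationarity condition
#' `b_ij = a_ij - (lambda_i + mu_j) / (2 w_ij)` turns the margin constraints
#' into an `(m+n)`-dimensional linear system for the duals (solved with
#' iterative refinement, since the system is singular by one per connected
#' support component); cells driven negative are clamped to the active set,
#' zero cells whose multiplier turns profitable are released, and the loop
#' repeats until the KKT conditions hold.  Typical problems finish in a
#' handful of iterations even at 100 x 100 with big-M weights.
#'
#' @param a reference `joint_table`.
#' @param r,c target margins.
#' @param big_M optional zero-cell weight override.
#' @param tol tolerance on the margin residual ([fitting_error()]).
#' @param max_iterations cap on active-set changes.
#' @return the fitted `joint_table`; diagnostics (`iterations`, `residual`,
#'   `objective`, `big_M`) in attribute `"diagnostics"`.
#' @export
qp_fit <- function(a, r, c, big_M = NULL, tol = 1e-9, max_iterations = 200L) {
  a <- validate_joint(a)
  r <- as_margin(r, a$row_values); c <- as_margin(c, a$col_values)
  m <- nrow(a$cells); n <- ncol(a$cells)
  if (length(r$probs) != m || length(c$probs) != n)
    cbjf_abort("DIMENSION_MISMATCH", "margin lengths do not match table")
  w <- fit_problem_weights(a, big_M)
  A <- a$cells; h <- 1 / (2 * w$w)
  rt <- r$probs; ct <- c$probs
  free <- matrix(TRUE, m, n)
  b <- A; it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    hf <- h * free
    Hr <- rowSums(hf); Hc <- colSums(hf)
    rhs <- c(rowSums(A * free) - rt, colSums(A * free) - ct)
    K0 <- rbind(cbind(diag(Hr, m), hf), cbind(t(hf), diag(Hc, n)))
    K <- K0 + diag(1e-10 * max(Hr, Hc), m + n)
    sol <- solve(K, rhs)
    for (polish in 1:4) {                   # refine away the ridge bias
      resid <- rhs - as.vector(K0 %*% sol)
      if (max(abs(resid)) < 1e-16) break
      sol <- sol + solve(K, resid)
    }
    lam <- sol[seq_len(m)]; mu <- sol[m + seq_len(n)]
    b <- (A - outer(lam, mu, `+`) * h) * free
    neg <- free & (b < -1e-14)
    viol <- (!free) & (A - outer(lam, mu, `+`) * h > 1e-14)
    if (!any(neg) && !any(viol)) break
    free[neg] <- FALSE
    free[viol] <- TRUE
  }
  b[b < 0] <- 0
  err <- max(abs(rowSums(b) - rt)) + max(abs(colSums(b) - ct))
  if (err >= tol)
    cbjf_warn("SOLVER_FAILURE",
              "QP active-set residual %.3g after %d iterations (tol %g)",
              err, it, tol)
  out <- joint_table(b / sum(b), a$row_values, a$col_values)
  attr(out, "diagnostics") <- list(
    iterations = it, residual = err,
    objective = sum(w$w * (b - A)^2), big_M = w$big_M)
  out
}

#' Weighted L1 joint fitting (LP baseline)
#'
#' Minimizes `sum_ij w_ij |b_ij - a_ij|` subject to exact target margins and
#' `b_ij >= 0`, via the standard split-variable linear program
#' (`b_ij - a_ij = Z+ - Z-`, both parts nonnegative), solved with
#' [boot::simplex()].  At the optimum at most one of each `(Z+, Z-)` pair is
#' nonzero.  The LP formulation is provided for completeness and
#' cross-checks; it is not part of the default benchmark set.  The dense
#' simplex solver limits practical sizes to a few hundred cells.
#'
#' @inheritParams qp_fit
#' @return the fitted `joint_table`; diagnostics (`objective`, `big_M`) in
#'   attribute `"diagnostics"`.
#' @export
lp_fit <- function(a, r, c, big_M = NULL) {
  a <- validate_joint(a)
  r <- as_margin(r, a$row_values); c <- as_margin(c, a$col_values)
  m <- nrow(a$cells); n <- ncol(a$cells)
  if (length(r$probs) != m || length(c$probs) != n)
    cbjf_abort("DIMENSION_MISMATCH", "margin lengths do not match table")
  w <- fit_problem_weights(a, big_M)
  mn <- m * n
  ## variables: [b (mn), Zp (mn), Zm (mn)], all >= 0
  nvar <- 3L * mn
  obj <- c(rep(0, mn), as.vector(w$w), as.vector(w$w))
  rowsel <- function(i) { A <- matrix(0, 1, nvar); A[1, i + m * (0:(n - 1))] <- 1; A }
  colsel <- function(j) { A <- matrix(0, 1, nvar); A[1, (j - 1) * m + 1:m] <- 1; A }
  A3 <- do.call(rbind, c(
    lapply(seq_len(m), rowsel),
    lapply(seq_len(n - 1), colsel),          # last column constraint redundant
    lapply(seq_len(mn), function(k) {
      A <- matrix(0, 1, nvar); A[1, k] <- 1
      A[1, mn + k] <- -1; A[1, 2L * mn + k] <- 1; A
    })
  ))
  b3 <- c(r$probs, c$probs[seq_len(n - 1)], as.vector(a$cells))
  sol <- boot::simplex(a = obj, A3 = A3, b3 = b3, maxi = FALSE,
                       n.iter = 100 * nvar)
  if (sol$solved != 1)
    cbjf_abort("SOLVER_FAILURE", "simplex did not solve (status %d)", sol$solved)
  b <- matrix(pmax(sol$soln[seq_len(mn)], 0), m, n)
  out <- joint_table(b / sum(b), a$row_values, a$col_values)
  attr(out, "diagnostics") <- list(
    objective = sum(w$w * abs(b - a$cells)), big_M = w$big_M,
    zplus = matrix(sol$soln[mn + seq_len(mn)], m, n),
    zminus = matrix(sol$soln[2L * mn + seq_len(mn)], m, n))
  out
}
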