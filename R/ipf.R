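#' Configuration for iterative proportional fitting
#'
#' @param tolerance convergence tolerance on the [fitting_error()] criterion.
#' @param max_iterations iteration cap; one iteration is one full row sweep
#'   followed by one full column sweep, with convergence tested after the pair.
#' @param zero_replacement substitute for zero cells at initialization
#'   (`0` = strict algorithm; the classical work-around uses e.g. `1e-20`,
#'   which lets mass cross otherwise block-separated supports).
#' @param check_block_structure if `TRUE`, a non-converged fit attaches a
#'   block-structure report (see [detect_block_structure()]) to its diagnostics.
#' @return a list of class `ipf_config`.
#' @export
ipf_config <- function(tolerance = 1e-5, max_iterations = 10000L,
                       zero_replacement = 0, check_block_structure = TRUE) {
  if (tolerance <= 0) cbjf_abort("INVALID_STRENGTH", "tolerance must be > 0")
  if (zero_replacement < 0)
    cbjf_abort("INVALID_STRENGTH", "zero_replacement must be >= 0")
  structure(list(tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 zero_replacement = zero_replacement,
                 check_block_structure = isTRUE(check_block_structure)),
            class = "ipf_config")
}

#' Iterative proportional fitting (matrix raking)
#'
#' Starting from `b = a`, alternately rescales rows to match `r` and columns
#' to match `c` until the [fitting_error()] drops below the tolerance.  Zero
#' cells of `a` stay zero throughout (unless `zero_replacement > 0`), and on
#' convergence the result minimizes the relative entropy `RE(b, a)` among all
#' margin-feasible tables.
#'
#' A row (or column) whose current margin is zero while its target is also
#' zero is set to all zeros; a zero reference margin facing a positive target
#' is a structural infeasibility and raises `ZERO_MARGIN`.  Non-convergence
#' within `max_iterations` returns the best table with `converged = FALSE`
#' and a `NOT_CONVERGED` warning (the usual cause is a block-diagonal
#' support; see [detect_block_structure()]).
#'
#' @param a reference `joint_table`.
#' @param r,c target margins.
#' @param config an [ipf_config()].
#' @return a list with elements `table` (the fitted `joint_table`) and
#'   `diagnostics` (iterations, fitting_error, relative_entropy, converged,
#'   tolerance, and optionally `blocks`).
#' @export
ipf_fit <- function(a, r, c, config = ipf_config()) {
  a <- validate_joint(a)
  r <- as_margin(r, a$row_values); c <- as_margin(c, a$col_values)
  m <- nrow(a$cells); n <- ncol(a$cells)
  if (length(r$probs) != m || length(c$probs) != n)
    cbjf_abort("DIMENSION_MISMATCH", "margin lengths do not match table")
  b <- a$cells
  if (config$zero_replacement > 0) {
    b[b == 0] <- config$zero_replacement
    b <- b / sum(b)
  }
  rt <- r$probs; ct <- c$probs
  if (any(rowSums(b) == 0 & rt > 0))
    cbjf_abort("ZERO_MARGIN", "reference row margin %d is zero but target is %g",
               which(rowSums(b) == 0 & rt > 0)[1],
               rt[which(rowSums(b) == 0 & rt > 0)[1]])
  if (any(colSums(b) == 0 & ct > 0))
    cbjf_abort("ZERO_MARGIN", "reference column margin %d is zero but target is %g",
               which(colSums(b) == 0 & ct > 0)[1],
               ct[which(colSums(b) == 0 & ct > 0)[1]])
  it <- 0L; err <- Inf
  while (it < config$max_iterations) {
    rm <- rowSums(b)
    b <- b * ifelse(rm > 0, rt / rm, 0)
    cm <- colSums(b)
    b <- sweep(b, 2L, ifelse(cm > 0, ct / cm, 0), `*`)
    it <- it + 1L
    err <- max(abs(rowSums(b) - rt)) + max(abs(colSums(b) - ct))
    if (err < config$tolerance) break
  }
  converged <- err < config$tolerance
  out <- joint_table(b / sum(b), a$row_values, a$col_values)
  diag <- list(iterations = it, fitting_error = err,
               relative_entropy = relative_entropy(out, a),
               converged = converged, tolerance = config$tolerance)
  if (!converged) {
    if (config$check_block_structure)
      diag$blocks <- detect_block_structure(a, r, c)
    cbjf_warn("NOT_CONVERGED",
              "IPF did not reach tolerance %g in %d iterations (error %.3g)",
              config$tolerance, it, err)
  }
  list(table = out, diagnostics = diag)
}

#' Diagnose support structure blocking IPF convergence
#'
#' IPF cannot move probability mass across zero cells.  Two related
#' diagnoses are reported.  First, the connected components of the bipartite
#' graph on rows and columns (an edge wherever `a_ij > 0`): with several
#' components ("block-diagonal" support after permutation), IPF can converge
#' only if each component's target row mass equals its target column mass.
#' Second, and more generally, a maximum-flow feasibility check of the target
#' margins on the support of `a`: IPF converges to a margin-exact table iff
#' some nonnegative table with that support has margins `(r, c)`, i.e. iff
#' the maximum flow from rows (capacities `r`) to columns (capacities `c`)
#' through the support equals 1.  A connected support can still be infeasible
#' (a row whose support covers too little column mass), in which case IPF
#' stalls at a positive fitting error equal to the flow deficit; the minimum
#' cut names the offending row/column groups.
#'
#' @param a reference `joint_table`.
#' @param r,c target margins.
#' @return a list with `n_components`, a data frame `components`
#'   (`rows`, `cols`, `ref_mass`, `target_row_mass`, `target_col_mass`),
#'   `flow_deficit` (1 minus the maximum flow), `cut_rows`/`cut_cols`
#'   (source-side row group and its reachable columns when infeasible), and
#'   `nonconvergent` (`TRUE` when components are unbalanced or the margins
#'   are infeasible on the support).
#' @export
detect_block_structure <- function(a, r, c) {
  a <- validate_joint(a)
  r <- as_margin(r, a$row_values); c <- as_margin(c, a$col_values)
  m <- nrow(a$cells); n <- ncol(a$cells)
  nz <- which(a$cells > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(m + n, directed = FALSE)
  if (nrow(nz) > 0L)
    g <- igraph::add_edges(g, rbind(nz[, 1], m + nz[, 2]))
  comp <- igraph::components(g)$membership
  ids <- sort(unique(comp))
  rows <- lapply(ids, function(k) which(comp[seq_len(m)] == k))
  cols <- lapply(ids, function(k) which(comp[m + seq_len(n)] == k))
  df <- data.frame(
    component = seq_along(ids),
    ref_mass = vapply(seq_along(ids), function(k)
      if (length(rows[[k]]) && length(cols[[k]]))
        sum(a$cells[rows[[k]], cols[[k]], drop = FALSE]) else 0,
      0),
    target_row_mass = vapply(rows, function(ix) sum(r$probs[ix]), 0),
    target_col_mass = vapply(cols, function(ix) sum(c$probs[ix]), 0)
  )
  df$rows <- I(rows); df$cols <- I(cols)

  ## max-flow feasibility of (r, c) on supp(a): source 1, rows, cols, sink
  s <- 1L; rid <- 1L + seq_len(m); cid <- 1L + m + seq_len(n); t <- m + n + 2L
  edges <- rbind(cbind(s, rid), cbind(rid[nz[, 1]], cid[nz[, 2]]), cbind(cid, t))
  caps <- c(r$probs, rep(2, nrow(nz)), c$probs)
  fg <- igraph::graph_from_edgelist(edges, directed = TRUE)
  mf <- igraph::max_flow(fg, source = s, target = t, capacity = caps)
  deficit <- max(0, 1 - mf$value)
  cut_rows <- integer(0); cut_cols <- integer(0)
  if (deficit > 1e-12) {
    side <- as.integer(mf$partition1)        # source side of a minimum cut
    cut_rows <- setdiff(side[side %in% rid], integer(0)) - 1L
    cut_cols <- side[side %in% cid] - 1L - m
  }
  list(n_components = length(ids),
       components = df,
       flow_deficit = deficit,
       cut_rows = as.integer(cut_rows), cut_cols = as.integer(cut_cols),
       nonconvergent =
         any(abs(df$target_row_mass - df$target_col_mass) > 1e-12) ||
         deficit > 1e-12)
}
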