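#' Synthetic reference joint distributions
#'
#' Builds the benchmark's reference joint tables: five bivariate families
#' discretized onto an equal-width bin grid (defaults reproduce the study
#' conditions: 100 bins per axis).
#'
#' * `normal`: bivariate normal, mean `(0, 0)`, unit standard deviations,
#'   correlation `rho = 0.7`.  Cell masses are exact rectangle probabilities
#'   (Gauss-Legendre quadrature of the conditional normal CDF, accurate to
#'   ~1e-12); bins span mean +/- 4 sd with the clipped tail mass folded into
#'   the edge bins.
#' * `bimodal`: equal-weight mixture of two bivariate normals,
#'   `mu1 = (0, 0), rho1 = 0.7` and `mu2 = (3, 1), rho2 = -0.5`, unit sds;
#'   exact rectangle probabilities; bins cover both components' +/- 4 sd.
#' * `tail_dependent`: a pair with strong lower tail dependence when `X` is
#'   low — a Clayton copula (`theta = 2`, lower tail dependent) mapped
#'   through standard-normal quantiles; exact via copula CDF differencing.
#' * `u_shape`: `X ~ uniform(-1, 1)`, `Y = X^2 + N(0, 0.1)` — near-zero
#'   linear correlation by symmetry; quadrature-exact cell masses.
#' * `circle`: angle `~ uniform(0, 2 pi)`, radius `1 + N(0, 0.1)`, Cartesian
#'   coordinates; built from a large-sample histogram (deterministic under
#'   `seed`), size `max(10 * bins^2, sample_size)`.
#'
#' @param family one of `"normal"`, `"bimodal"`, `"tail_dependent"`,
#'   `"u_shape"`, `"circle"`.
#' @param bins bins per axis (>= 2).
#' @param rho correlation of the `normal` family.
#' @param theta Clayton parameter of the `tail_dependent` family.
#' @param noise_sd noise standard deviation of the `u_shape` and `circle`
#'   families.
#' @param sample_size histogram sample size for the `circle` family.
#' @param seed RNG seed for histogram construction.
#' @return a `joint_table` with bin centers as category values.
#' @export
make_reference_joint <- function(family = c("normal", "bimodal",
                                            "tail_dependent", "u_shape",
                                            "circle"),
                                 bins = 100L, rho = 0.7, theta = 2,
                                 noise_sd = 0.1, sample_size = NULL,
                                 seed = 1L) {
  family <- match.arg(family)
  bins <- as.integer(bins)
  if (bins < 2L) cbjf_abort("DEGENERATE_BINS", "need at least 2 bins per axis")
  switch(family,
    normal = {
      xe <- seq(-4, 4, length.out = bins + 1L)
      cells <- bvn_rect_probs(xe, xe, c(0, 0), c(1, 1), rho, clip = TRUE)
      joint_table(cells / sum(cells), centers(xe), centers(xe))
    },
    bimodal = {
      xe <- seq(-4, 7, length.out = bins + 1L)
      ye <- seq(-4, 5, length.out = bins + 1L)
      cells <- 0.5 * bvn_rect_probs(xe, ye, c(0, 0), c(1, 1), 0.7, clip = TRUE) +
        0.5 * bvn_rect_probs(xe, ye, c(3, 1), c(1, 1), -0.5, clip = TRUE)
      joint_table(cells / sum(cells), centers(xe), centers(ye))
    },
    tail_dependent = {
      xe <- seq(-4, 4, length.out = bins + 1L)
      ue <- stats::pnorm(xe); ue[1] <- 0; ue[length(ue)] <- 1
      Cuv <- outer(ue, ue, clayton_cdf, theta = theta)
      cells <- diff2(Cuv)
      cells[cells < 0] <- 0
      joint_table(cells / sum(cells), centers(xe), centers(xe))
    },
    u_shape = {
      xe <- seq(-1, 1, length.out = bins + 1L)
      ye <- seq(0 - 4 * noise_sd, 1 + 4 * noise_sd, length.out = bins + 1L)
      cells <- ushape_rect_probs(xe, ye, noise_sd)
      joint_table(cells / sum(cells), centers(xe), centers(ye))
    },
    circle = {
      n <- max(10 * bins^2, sample_size %||% 0)
      pts <- with_seed(seed, {
        ang <- stats::runif(n, 0, 2 * pi)
        rad <- 1 + stats::rnorm(n, 0, noise_sd)
        cbind(rad * cos(ang), rad * sin(ang))
      })
      lim <- max(abs(pts))
      xe <- seq(-lim, lim, length.out = bins + 1L)
      h <- table(
        factor(findInterval(pts[, 1], xe, rightmost.closed = TRUE,
                            all.inside = TRUE), levels = seq_len(bins)),
        factor(findInterval(pts[, 2], xe, rightmost.closed = TRUE,
                            all.inside = TRUE), levels = seq_len(bins)))
      cells <- matrix(as.numeric(h), bins, bins)
      joint_table(cells / sum(cells), centers(xe), centers(xe))
    }
  )
}

#' @keywords internal
centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' @keywords internal
diff2 <- function(M) {
  M[-1, -1, drop = FALSE] - M[-nrow(M), -1, drop = FALSE] -
    M[-1, -ncol(M), drop = FALSE] + M[-nrow(M), -ncol(M), drop = FALSE]
}

#' @keywords internal
clayton_cdf <- function(u, v, theta) {
  out <- pmax(u^(-theta) + v^(-theta) - 1, 0)^(-1 / theta)
  out[u == 0 | v == 0] <- 0
  out[u == 1] <- v[u == 1]
  out[v == 1] <- u[v == 1]
  out
}

## Exact bivariate-normal rectangle probabilities on a grid:
## P = int_xbin phi(x) [Phi(h(y_hi, x)) - Phi(h(y_lo, x))] dx with
## h(y, x) = (y - muy - rho sy (x - mux)/sx) / (sy sqrt(1 - rho^2)),
## by 16-node Gauss-Legendre per x bin.  With clip = TRUE the outer edges
## extend to +/- 8 sd so tail mass folds into the edge bins.
#' @keywords internal
bvn_rect_probs <- function(xedges, yedges, mu, sd, rho, clip = FALSE) {
  m <- length(xedges) - 1L; n <- length(yedges) - 1L
  xe <- xedges; ye <- yedges
  if (clip) {
    xe[1] <- mu[1] - 8 * sd[1]; xe[m + 1L] <- mu[1] + 8 * sd[1]
    ye[1] <- mu[2] - 8 * sd[2]; ye[n + 1L] <- mu[2] + 8 * sd[2]
  }
  gl <- pracma::gaussLegendre(16, -1, 1)
  mids <- (xe[-1] + xe[-(m + 1L)]) / 2
  halfw <- (xe[-1] - xe[-(m + 1L)]) / 2
  nodes <- outer(mids, rep(1, 16L)) + outer(halfw, gl$x)
  z <- (nodes - mu[1]) / sd[1]
  dens <- stats::dnorm(z) / sd[1]
  condsd <- sd[2] * sqrt(1 - rho^2)
  condmu <- mu[2] + rho * sd[2] * z
  ## cumulative over y edges at each node, then difference
  FY <- vapply(ye, function(yy) stats::pnorm((yy - condmu) / condsd),
               matrix(0, m, 16L))
  cells <- matrix(0, m, n)
  for (j in seq_len(n)) {
    integrand <- dens * (FY[, , j + 1L] - FY[, , j])
    cells[, j] <- halfw * (integrand %*% gl$w)
  }
  pmax(cells, 0)
}

## Quadrature cell masses for X ~ U(-1,1), Y = X^2 + N(0, sd).
#' @keywords internal
ushape_rect_probs <- function(xedges, yedges, sd) {
  m <- length(xedges) - 1L; n <- length(yedges) - 1L
  ye <- yedges; ye[1] <- -Inf; ye[n + 1L] <- Inf
  gl <- pracma::gaussLegendre(16, -1, 1)
  mids <- (xedges[-1] + xedges[-(m + 1L)]) / 2
  halfw <- (xedges[-1] - xedges[-(m + 1L)]) / 2
  nodes <- outer(mids, rep(1, 16)) + outer(halfw, gl$x)
  dens <- 0.5   # uniform(-1, 1) density
  FY <- vapply(ye, function(yy) stats::pnorm((yy - nodes^2) / sd),
               matrix(0, m, 16L))
  cells <- matrix(0, m, n)
  for (j in seq_len(n))
    cells[, j] <- halfw * ((dens * (FY[, , j + 1L] - FY[, , j])) %*% gl$w)
  pmax(cells, 0)
}

#' Marginal modification operators
#'
#' Parametric reweightings that turn a reference margin into a target margin,
#' continuous in `strength` with the identity at 0 (skew/fat/thin):
#'
#' * `skew_left` / `skew_right`: reweight bin `k` by the linear ramp
#'   `1 - s + 2 s (k-1)/(n-1)` (right; mirrored for left), `s` in `[0, 1)`.
#' * `uniform`: every bin `1/n` regardless of strength.
#' * `fat_tail` / `thin_tail`: reweight by `exp(+/- s d_k)` with `d_k` the
#'   normalized distance of bin `k` from the central bin (`d` in `[0, 1]`).
#' * `perturb`: multiply each bin by `1 + s xi_k`, `xi_k` i.i.d.
#'   uniform(-1, 1) under `seed`; `s = 0.1` is the classic "+/- 10% noise".
#'
#' All outputs are renormalized to sum to 1.
#'
#' @param margin a `margin_vector` (or probability vector).
#' @param operator operator name.
#' @param strength nonnegative strength `s` (skew requires `s < 1`).
#' @param seed RNG seed (perturb only).
#' @return a valid `margin_vector` on the same category values.
#' @export
apply_margin_operator <- function(margin,
                                  operator = c("skew_left", "skew_right",
                                               "uniform", "fat_tail",
                                               "thin_tail", "perturb"),
                                  strength = NULL, seed = 1L) {
  operator <- match.arg(operator)
  margin <- as_margin(margin)
  p <- margin$probs; n <- length(p)
  strength <- strength %||%
    switch(operator, skew_left = 0.5, skew_right = 0.5, uniform = 0,
           fat_tail = 2, thin_tail = 2, perturb = 0.1)
  if (strength < 0 || (operator %in% c("skew_left", "skew_right") &&
                       strength >= 1))
    cbjf_abort("INVALID_STRENGTH", "invalid strength %g for %s",
               strength, operator)
  k <- seq_len(n)
  w <- switch(operator,
    skew_right = 1 - strength + 2 * strength * (k - 1) / (n - 1),
    skew_left  = 1 - strength + 2 * strength * (n - k) / (n - 1),
    uniform    = 1 / p,            # flattens to exactly 1/n
    fat_tail   = exp(strength * center_dist(n)),
    thin_tail  = exp(-strength * center_dist(n)),
    perturb    = 1 + strength * with_seed(seed, stats::runif(n, -1, 1))
  )
  q <- p * w
  if (operator == "uniform") q <- rep(1, n)
  margin_vector(q / sum(q), margin$values)
}

#' @keywords internal
center_dist <- function(n) abs(seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)

#' The benchmark's eight marginal modification cases
#'
#' Expands an operator case name into per-axis operators: the four skew
#' combinations modify the two axes independently (`skew_lr` = row margin
#' skewed left, column margin skewed right, and so on); `uniform`,
#' `fat_tail`, `thin_tail` apply the same operator to both axes; `perturb`
#' applies independent noise per axis.
#'
#' @return named list mapping case name to `c(row_operator, col_operator)`.
#' @export
margin_operator_cases <- function() {
  list(
    skew_ll = c("skew_left", "skew_left"),
    skew_rr = c("skew_right", "skew_right"),
    skew_lr = c("skew_left", "skew_right"),
    skew_rl = c("skew_right", "skew_left"),
    uniform = c("uniform", "uniform"),
    fat_tail = c("fat_tail", "fat_tail"),
    thin_tail = c("thin_tail", "thin_tail"),
    perturb = c("perturb", "perturb")
  )
}

## Build the target margins of one benchmark case.
#' @keywords internal
case_margins <- function(ref, case, strength = NULL, seed = 1L) {
  ops <- margin_operator_cases()[[case]]
  if (is.null(ops)) cbjf_abort("UNKNOWN_FAMILY", "unknown case %s", case)
  r0 <- row_margins(ref); c0 <- col_margins(ref)
  list(
    r = apply_margin_operator(r0, ops[1], strength = strength, seed = seed),
    c = apply_margin_operator(c0, ops[2], strength = strength, seed = seed + 1L)
  )
}

#' Run the dependence-preservation benchmark grid
#'
#' For each combination of reference family and marginal modification case:
#' build the reference table, derive target margins, fit with each method,
#' and measure dependence preservation ([dependence_report()]) plus the
#' marginal variation of the case.  The default grid (5 families x 8 cases)
#' is the study's 40-combination test set.
#'
#' @param families reference families (see [make_reference_joint()]).
#' @param cases case names (see [margin_operator_cases()]).
#' @param methods fitters to compare: subset of `"ipf"`, `"cbjf"`, `"qp"`.
#' @param bins bins per axis.
#' @param mic_samples,seed MIC sampling controls.
#' @return a long-format data frame with one row per
#'   (family, case, method): the four observed measures, their absolute
#'   deviations from the reference, `marginal_variation`, and the method's
#'   `fitting_error`.  Reference measures are attached as attribute
#'   `"reference_measures"`.
#' @export
run_benchmark <- function(families = c("normal", "bimodal", "tail_dependent",
                                       "u_shape", "circle"),
                          cases = names(margin_operator_cases()),
                          methods = c("ipf", "cbjf", "qp"),
                          bins = 100L, mic_samples = 10000L, seed = 1L) {
  rows <- list(); refmeas <- list()
  for (fam in families) {
    ref <- make_reference_joint(fam, bins = bins, seed = seed)
    r0 <- row_margins(ref); c0 <- col_margins(ref)
    for (cs in cases) {
      tg <- case_margins(ref, cs, seed = seed)
      mv <- marginal_variation(r0, c0, tg$r, tg$c)
      for (me in methods) {
        fit <- try(fit_with_method(me, ref, tg$r, tg$c), silent = TRUE)
        if (inherits(fit, "try-error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            family = fam, case = cs, method = me, error = TRUE,
            marginal_variation = mv, pearson = NA, spearman = NA,
            kendall = NA, mic = NA, dev_pearson = NA, dev_spearman = NA,
            dev_kendall = NA, dev_mic = NA, fitting_error = NA)
          next
        }
        rep <- dependence_report(fit, ref, mic_samples = mic_samples,
                                 seed = seed, jitter = TRUE)
        refmeas[[fam]] <- rep$reference
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, case = cs, method = me, error = FALSE,
          marginal_variation = mv,
          pearson = rep$measures[["pearson"]],
          spearman = rep$measures[["spearman"]],
          kendall = rep$measures[["kendall"]],
          mic = rep$measures[["mic"]],
          dev_pearson = rep$deviations[["pearson"]],
          dev_spearman = rep$deviations[["spearman"]],
          dev_kendall = rep$deviations[["kendall"]],
          dev_mic = rep$deviations[["mic"]],
          fitting_error = fitting_error(fit, tg$r, tg$c))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference_measures") <- refmeas
  out
}

#' @keywords internal
fit_with_method <- function(method, a, r, c) {
  switch(method,
    ipf = suppressWarnings(
      ipf_fit(a, r, c, ipf_config(tolerance = 1e-8,
                                  zero_replacement = 1e-20))$table),
    cbjf = cbjf_fit(a, r, c),
    qp = suppressWarnings(qp_fit(a, r, c, tol = 1e-8)),
    lp = lp_fit(a, r, c),
    cbjf_abort("UNKNOWN_FAMILY", "unknown method %s", method)
  )
}

#' Marginal-variation sweep
#'
#' Applies one strength-parameterized operator (skew/fat/thin) at increasing
#' strengths, fits with each method, and records the marginal variation and
#' the MIC absolute deviation — tracing how dependence preservation degrades
#' as the margins move away from the reference.
#'
#' @param family reference family.
#' @param operator one of the strength-parameterized operators
#'   (`skew_left`, `skew_right`, `fat_tail`, `thin_tail`).
#' @param strengths increasing strength schedule (default: 8 levels spanning
#'   marginal variation roughly 0 to 0.5 on the normal family).
#' @param methods fitters to compare.
#' @inheritParams run_benchmark
#' @return data frame with one row per (strength, method):
#'   `marginal_variation`, `mic`, `dev_mic`.
#' @export
variation_sweep <- function(family = "normal", operator = "fat_tail",
                            strengths = NULL,
                            methods = c("ipf", "cbjf", "qp"),
                            bins = 100L, mic_samples = 10000L, seed = 1L) {
  if (!operator %in% c("skew_left", "skew_right", "fat_tail", "thin_tail"))
    cbjf_abort("INVALID_STRENGTH", "%s has no strength parameter", operator)
  strengths <- strengths %||%
    if (startsWith(operator, "skew")) seq(0, 0.98, length.out = 8)
    else seq(0, 3.5, length.out = 8)
  ref <- make_reference_joint(family, bins = bins, seed = seed)
  r0 <- row_margins(ref); c0 <- col_margins(ref)
  mic_ref <- mic(sample_from_table(ref, mic_samples, seed = seed, jitter = TRUE))
  rows <- list()
  for (s in strengths) {
    r1 <- apply_margin_operator(r0, operator, strength = s)
    c1 <- apply_margin_operator(c0, operator, strength = s)
    mv <- marginal_variation(r0, c0, r1, c1)
    for (me in methods) {
      fit <- fit_with_method(me, ref, r1, c1)
      mic_fit <- mic(sample_from_table(fit, mic_samples, seed = seed,
                                       jitter = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        strength = s, method = me, marginal_variation = mv,
        mic = mic_fit, dev_mic = abs(mic_ref - mic_fit))
    }
  }
  do.call(rbind, rows)
}
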