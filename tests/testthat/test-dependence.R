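product_table <- function(m, n, seed) {
  r <- random_margin(m, seed)$probs
  c <- random_margin(n, seed + 1)$probs
  joint_table(outer(r, c))
}

test_that("all correlation measures vanish exactly on product tables", {
  for (seed in 1:5) {
    tab <- product_table(5, 4, seed)
    expect_equal(pearson_from_table(tab), 0, tolerance = 1e-12)
    expect_equal(spearman_from_table(tab), 0, tolerance = 1e-12)
    expect_equal(kendall_from_table(tab), 0, tolerance = 1e-12)
  }
})

test_that("perfect diagonal dependence gives the known values", {
  for (m in 2:6) {
    tab <- joint_table(diag(m) / m)
    expect_equal(pearson_from_table(tab), 1)
    expect_equal(spearman_from_table(tab), 1)
    ## tau has no tie correction: (m - 1)/m, confirmed by enumeration
    expect_equal(kendall_from_table(tab), (m - 1) / m)
    expect_equal(kendall_brute(tab), (m - 1) / m, tolerance = 1e-12)
  }
})

test_that("two-by-two hand examples", {
  tab <- joint_table(matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2),
                     row_values = c(0, 1), col_values = c(0, 1))
  expect_equal(pearson_from_table(tab), 0.6)
  ## two-point margins make the CDF transform affine: s = rho
  expect_equal(spearman_from_table(tab), 0.6)
  half <- joint_table(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(kendall_from_table(half), 0.5)
})

test_that("kendall matrix formula equals the brute-force pair enumeration", {
  for (seed in 1:5) {
    tab <- random_table(3L + seed %% 5L, 3L + (seed + 2L) %% 5L, seed,
                        zero_frac = 0.2)
    expect_equal(kendall_from_table(tab), kendall_brute(tab),
                 tolerance = 1e-12)
  }
})

test_that("negating an axis order negates the correlations", {
  for (seed in 1:5) {
    tab <- random_table(5, 6, seed)
    rev_tab <- joint_table(tab$cells[5:1, ],
                           row_values = -rev(tab$row_values),
                           col_values = tab$col_values)
    ## reversing rows with negated values flips the sign of X
    expect_equal(pearson_from_table(rev_tab), -pearson_from_table(tab))
    expect_equal(kendall_from_table(rev_tab), -kendall_from_table(tab))
    ## under the at-the-atom CDF convention the transform of -X is
    ## 1 - F(X) + P[X = x], so antisymmetry holds only up to O(sum p^2);
    ## the mid-rank convention is exactly antisymmetric
    expect_equal(spearman_from_table(rev_tab, midrank = TRUE),
                 -spearman_from_table(tab, midrank = TRUE), tolerance = 1e-12)
    ## default (at-the-atom) convention: sign flips (up to correlations
    ## indistinguishable from zero, where the sign is not identified)
    expect_lt(spearman_from_table(rev_tab) * spearman_from_table(tab), 1e-6)
  }
})

test_that("spearman is pearson on the CDF-revalued table", {
  for (seed in 1:5) {
    tab <- random_table(6, 4, seed)
    u <- cumsum(rowSums(tab$cells)); v <- cumsum(colSums(tab$cells))
    revalued <- joint_table(tab$cells, u, v)
    expect_equal(spearman_from_table(tab), pearson_from_table(revalued))
  }
})

test_that("zero-variance margins are rejected", {
  expect_error(pearson_from_table(joint_table(matrix(c(1, 0, 0, 0), 2, 2))),
               class = "ZERO_VARIANCE")
})

test_that("table sampling is reproducible and follows the masses", {
  one <- joint_table(matrix(1, 1, 1), 3, 7)
  pts <- sample_from_table(one, 10, seed = 1)
  expect_true(all(pts[, 1] == 3 & pts[, 2] == 7))
  tab <- random_table(4, 3, 5)
  expect_identical(sample_from_table(tab, 500, seed = 2),
                   sample_from_table(tab, 500, seed = 2))
  pts <- sample_from_table(tab, 100000, seed = 3)
  obs <- table(factor(pts[, 1], levels = 1:4), factor(pts[, 2], levels = 1:3))
  gof <- suppressWarnings(
    stats::chisq.test(as.vector(obs), p = as.vector(tab$cells)))
  expect_gt(gof$p.value, 0.001)
})

test_that("sampled estimates agree with the exact table formulas", {
  tab <- random_table(6, 5, 17)
  n <- 200000
  pts <- sample_from_table(tab, n, seed = 11)
  ## plug-in estimates from the empirical table of the sample
  emp <- table(factor(pts[, 1], levels = 1:6), factor(pts[, 2], levels = 1:5))
  emp <- joint_table(matrix(as.numeric(emp) / n, 6, 5))
  rho <- pearson_from_table(tab)
  ## 3 standard errors, conservative normal-theory scales
  expect_lt(abs(pearson_from_table(emp) - rho), 3 * (1 - rho^2 + 0.1) / sqrt(n))
  expect_lt(abs(spearman_from_table(emp) - spearman_from_table(tab)),
            3 * 1.1 / sqrt(n))
  expect_lt(abs(kendall_from_table(emp) - kendall_from_table(tab)),
            3 * 2 / sqrt(n))
})

test_that("MIC behaves at its anchor points", {
  x <- seq(0, 1, length.out = 2000)
  expect_gte(mic(x, x), 0.99)                      # noiseless function
  expect_gte(mic(x, (x - 0.5)^2), 0.99)            # non-monotone function
  pts <- withr::with_seed(5, cbind(stats::runif(10000), stats::runif(10000)))
  expect_lt(mic(pts), 0.15)                        # independence null
  expect_error(mic(rep(1, 100), stats::runif(100)),
               class = "DEGENERATE_INPUT")
})

test_that("dependence report deviations are zero against itself", {
  tab <- random_table(20, 20, 23)
  rep <- dependence_report(tab, tab, mic_samples = 4000, seed = 3)
  expect_equal(unname(rep$deviations), rep(0, 4))
  expect_true(all(rep$measures >= -1 & rep$measures <= 1))
})
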