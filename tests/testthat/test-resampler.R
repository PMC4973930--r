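make_records <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    x = stats::runif(n, 0, 10),
    y = stats::runif(n, 0, 6),
    z1 = sample(letters[1:4], n, replace = TRUE),
    z2 = stats::rnorm(n)
  ))
}

test_that("resampling weights aggregate to the distribution-view fit", {
  xb <- seq(0, 10, by = 2); yb <- seq(0, 6, by = 2)
  for (seed in 1:5) {
    recs <- make_records(40, seed)
    r <- random_margin(5, seed + 1); c <- random_margin(3, seed + 2)
    pool <- cbjf_resample(recs, xb, yb, r, c)
    expect_equal(sum(pool$w), 1, tolerance = 1e-12)
    ## empirical joint of the records
    emp <- matrix(0, 5, 3)
    i <- findInterval(recs$x, xb, rightmost.closed = TRUE, all.inside = TRUE)
    j <- findInterval(recs$y, yb, rightmost.closed = TRUE, all.inside = TRUE)
    for (k in seq_len(nrow(recs))) emp[i[k], j[k]] <- emp[i[k], j[k]] + 1 / 40
    ref <- cbjf_distribute(joint_table(emp), r, c)
    agg <- aggregate_weights(pool, r, c)
    expect_lt(max(abs(agg$cells - ref$cells)), 1e-12)
    ## z attributes survive with the multiplicity of their source records
    expect_identical(sort(unique(paste(pool$src, pool$z1))),
                     sort(paste(seq_len(40), recs$z1)))
  }
})

test_that("one-dimensional overlap weights match the hand calculation", {
  ## two records in x-halves of the unit interval, one y bin, target (0.6, 0.4)
  recs <- data.frame(x = c(0.25, 0.75), y = c(0.5, 0.5))
  pool <- cbjf_resample(recs, x_breaks = c(0, 0.5, 1), y_breaks = c(0, 1),
                        r = margin_vector(c(0.6, 0.4)), c = margin_vector(1))
  p1 <- pool[pool$src == 1, ]; p2 <- pool[pool$src == 2, ]
  ## record 1 occupies [0, 0.5] inside target cell [0, 0.6]: one copy, w = 1/2
  expect_equal(nrow(p1), 1L); expect_equal(p1$w, 0.5)
  ## record 2 occupies [0.5, 1]: overlaps [0, 0.6] by 0.1/0.5 and
  ## [0.6, 1] by 0.4/0.5, each divided by N = 2
  expect_equal(sort(p2$w), c(0.1, 0.4))
})

test_that("resampling with matching margins is a weighted identity", {
  recs <- make_records(30, 11)
  xb <- seq(0, 10, by = 2.5); yb <- seq(0, 6, by = 3)
  i <- findInterval(recs$x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  j <- findInterval(recs$y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  r <- margin_vector(tabulate(i, 4) / 30)
  c <- margin_vector(tabulate(j, 2) / 30)
  pool <- cbjf_resample(recs, xb, yb, r, c)
  expect_equal(nrow(pool), 30L)
  expect_true(all(abs(pool$w - 1 / 30) < 1e-12))
})

test_that("records outside the bin edges are rejected", {
  recs <- data.frame(x = c(0.5, 2.5), y = c(0.5, 0.5))
  expect_error(
    cbjf_resample(recs, c(0, 1, 2), c(0, 1),
                  margin_vector(c(0.5, 0.5)), margin_vector(1)),
    class = "UNBINNABLE_RECORD")
  expect_error(cbjf_resample(data.frame(x = numeric(), y = numeric()),
                             c(0, 1), c(0, 1), margin_vector(1),
                             margin_vector(1)),
               class = "EMPTY_SET")
})

test_that("continuous transform follows ranks through the target quantiles", {
  recs <- data.frame(x = c(1, 2, 3, 4), y = c(4, 3, 2, 1))
  out <- cbjf_continuous(recs, function(u) u, function(u) u)
  expect_equal(out$x, c(0.25, 0.5, 0.75, 1))   # x = 3 maps to rank 3/4
  expect_equal(out$y, c(1, 0.75, 0.5, 0.25))
  ## rank preservation under strictly monotone quantiles (finite on (0, 1])
  recs2 <- make_records(50, 21)
  out2 <- cbjf_continuous(recs2, function(u) stats::qbeta(u, 2, 3),
                          function(u) stats::qunif(u, -5, 5))
  expect_equal(order(out2$x), order(recs2$x))
  expect_equal(order(out2$y), order(recs2$y))
  expect_identical(out2$z1, recs2$z1)
})

test_that("empirical target quantiles reproduce the order statistics", {
  recs <- make_records(40, 31)
  qx <- function(u) stats::quantile(recs$x, u, type = 1, names = FALSE)
  qy <- function(u) stats::quantile(recs$y, u, type = 1, names = FALSE)
  out <- cbjf_continuous(recs, qx, qy)
  expect_equal(out$x, recs$x)   # F^{-1}(i/N) on the empirical CDF
  expect_equal(out$y, recs$y)
})

test_that("tied records share rank and transform", {
  recs <- data.frame(x = c(1, 1, 2), y = c(5, 6, 7))
  out <- cbjf_continuous(recs, function(u) u, function(u) u)
  expect_equal(out$x[1], out$x[2])
  expect_equal(out$x[1], 2 / 3)   # ties take the maximal rank
})

test_that("population draws are reproducible and follow the weights", {
  single <- data.frame(x = 1, y = 2, w = 1)
  drawn <- draw_population(single, 50, seed = 4)
  expect_true(all(drawn$x == 1))
  recs <- make_records(25, 41)
  xb <- seq(0, 10, by = 2); yb <- seq(0, 6, by = 2)
  r <- random_margin(5, 42); c <- random_margin(3, 43)
  pool <- cbjf_resample(recs, xb, yb, r, c)
  d1 <- draw_population(pool, 1000, seed = 7)
  d2 <- draw_population(pool, 1000, seed = 7)
  expect_identical(d1, d2)
  ## empirical (x, y) frequencies converge to the aggregated weights
  big <- draw_population(pool, 100000, seed = 8)
  agg <- aggregate_weights(pool, r, c)
  key <- paste(big$x, big$y)
  cells <- expand.grid(i = 1:5, j = 1:3)
  expw <- agg$cells[cbind(cells$i, cells$j)]
  obs <- tabulate(match(key, paste(r$values[cells$i], c$values[cells$j])),
                  nrow(cells))
  keep <- expw > 0
  gof <- stats::chisq.test(obs[keep], p = expw[keep] / sum(expw[keep]))
  expect_gt(gof$p.value, 0.001)
})
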