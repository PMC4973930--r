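test_that("cumulative grid holds the joint CDF and marginal breakpoints", {
  g <- cumulative_grid(worked$a)
  expect_equal(g$u, c(0, 0.04, 0.16, 0.36, 0.56, 0.80, 0.92, 1.0))
  expect_equal(g$v, c(0, 0.12, 0.28, 0.64, 0.92, 1.0))
  ## mass of the 2x2 upper-left block: 0.04 + 0.08 + 0.04
  expect_equal(g$A[3, 3], 0.16)
  expect_equal(g$A[8, 6], 1)
  ## uniform-margin boundary rows/columns
  expect_equal(g$A[, 6], g$u)
  expect_equal(g$A[8, ], g$v)
})

test_that("locate maps points to unique cells with bilinear coordinates", {
  g <- cumulative_grid(worked$a)
  loc <- copula_locate(g, 0.07, 0.16)
  ## the cell [0.04, 0.16] x [0.12, 0.28]; s = 0.03/0.12, t = 0.04/0.16
  expect_equal(loc$i, 2L); expect_equal(loc$j, 2L)
  expect_equal(loc$s, 0.25); expect_equal(loc$t, 0.25)
  corner0 <- copula_locate(g, 0, 0)
  expect_equal(corner0$i, 1L); expect_equal(corner0$s, 0)
  corner1 <- copula_locate(g, 1, 1)
  expect_equal(corner1$i, 7L); expect_equal(corner1$s, 1)
  expect_error(copula_locate(g, -0.1, 0.5), class = "OUT_OF_RANGE")
  ## zero-width intervals are skipped: every probe lands in a
  ## positive-width cell even when margins have empty bins
  tab <- joint_table(matrix(c(0.5, 0, 0.5, 0, 0, 0, 0.0, 0, 0), 3, 3,
                            byrow = TRUE) / 1)
  g2 <- cumulative_grid(tab)
  for (q in c(0, 0.3, 0.5, 0.9, 1)) {
    l <- copula_locate(g2, q, q)
    expect_gt(g2$u[l$i + 1L], g2$u[l$i])
  }
})

test_that("the interpolated copula satisfies the copula laws", {
  probes <- seq(0, 1, length.out = 101)
  for (seed in 1:5) {
    tab <- random_table(7, 6, seed, zero_frac = 0.3)
    g <- cumulative_grid(tab)
    ## (a) uniform margins
    expect_equal(copula_eval(g, probes, rep(1, 101)), probes, tolerance = 1e-12)
    expect_equal(copula_eval(g, rep(1, 101), probes), probes, tolerance = 1e-12)
    expect_equal(copula_eval(g, probes, rep(0, 101)), rep(0, 101))
    expect_equal(copula_eval(g, rep(0, 101), probes), rep(0, 101))
    ## (b) monotone in each argument and (c) rectangle inequality,
    ## checked on the full 101 x 101 probe grid
    Cm <- outer(probes, probes, function(u, v) copula_eval(g, u, v))
    expect_true(all(diff(Cm) >= -1e-12))          # rows: increasing in u
    expect_true(all(t(diff(t(Cm))) >= -1e-12))    # cols: increasing in v
    rect <- diff(t(diff(t(Cm))))
    expect_true(all(rect >= -1e-12))
  }
})

test_that("copula evaluation matches the hand-worked value", {
  g <- cumulative_grid(worked$a)
  expect_equal(copula_eval(g, 0.07, 0.16),
               0.5625 * 0.04 + 0.1875 * 0.04 + 0.1875 * 0.12 + 0.0625 * 0.16)
})

test_that("cbjf_fit reproduces the worked example", {
  b <- cbjf_fit(worked$a, worked$r, worked$c)
  expect_lt(max(abs(b$cells - table_cbjf_expected)), 1e-3)
  expect_equal(b$cells[1, 1], 0.0625, tolerance = 1e-12)
  expect_equal(b$cells[1, 2], 0.0075, tolerance = 1e-12)
  ## probability diffuses into reference zero cells
  expect_equal(worked$a$cells[3, 1], 0)
  expect_gt(b$cells[3, 1], 0)
})

test_that("cbjf_fit is margin-exact, mass-conserving, nonnegative", {
  for (seed in 1:10) {
    a <- random_table(8, 6, seed, zero_frac = 0.4)
    r <- random_margin(8, seed + 50); c <- random_margin(6, seed + 60)
    b <- cbjf_fit(a, r, c)
    expect_lt(fitting_error(b, r, c), 1e-12)
    expect_equal(sum(b$cells), 1, tolerance = 1e-12)
    expect_true(all(b$cells >= 0))
  }
})

test_that("cbjf_fit is the identity at the reference margins", {
  for (seed in 1:5) {
    a <- random_table(6, 5, seed, zero_frac = 0.3)
    b <- cbjf_fit(a, row_margins(a), col_margins(a))
    expect_equal(b$cells, a$cells, tolerance = 1e-13)
  }
})

test_that("reversing both axes of all inputs reverses the output", {
  for (seed in 1:5) {
    a <- random_table(6, 4, seed, zero_frac = 0.2)
    r <- random_margin(6, seed + 5); c <- random_margin(4, seed + 6)
    b <- cbjf_fit(a, r, c)
    arev <- joint_table(a$cells[6:1, 4:1])
    brev <- cbjf_fit(arev, margin_vector(rev(r$probs)),
                     margin_vector(rev(c$probs)))
    expect_equal(brev$cells[6:1, 4:1], b$cells, tolerance = 1e-12)
  }
})

test_that("collection and distribution views agree", {
  for (seed in 1:10) {
    m <- 2L + (seed * 3L) %% 11L; n <- 2L + (seed * 5L) %% 11L
    a <- random_table(m, n, seed, zero_frac = 0.5)
    r <- random_margin(m, seed + 70); c <- random_margin(n, seed + 80)
    b1 <- cbjf_fit(a, r, c)
    b2 <- cbjf_distribute(a, r, c)
    expect_lt(max(abs(b1$cells - b2$cells)), 1e-10)
  }
})

test_that("distribution view handles sparse input and degenerate grids", {
  ## a single unit cell spreads as the product of the target margins
  one <- joint_table(matrix(1, 1, 1))
  r <- margin_vector(c(0.2, 0.5, 0.3)); c <- margin_vector(c(0.6, 0.4))
  b <- cbjf_distribute(one, r, c)
  expect_equal(b$cells, outer(r$probs, c$probs), tolerance = 1e-14)
  ## same reference and target grid: support and masses unchanged
  a <- random_table(5, 5, 3, zero_frac = 0.4)
  trip <- cbjf_distribute(a, row_margins(a), col_margins(a), sparse = TRUE)
  dense <- matrix(0, 5, 5)
  dense[cbind(trip$i, trip$j)] <- trip$mass
  expect_equal(dense, a$cells, tolerance = 1e-13)
  ## sparse triple input with duplicate coordinates sums on ingestion
  df <- data.frame(i = c(1, 1, 2), j = c(1, 1, 2), mass = c(0.3, 0.2, 0.5))
  b2 <- cbjf_distribute(df, margin_vector(c(0.5, 0.5)),
                        margin_vector(c(0.5, 0.5)))
  expect_equal(sum(b2$cells), 1, tolerance = 1e-12)
})
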