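## Shared fixtures: the worked 7x5 example and random-problem generators.

worked <- example_joint_problem()

## Printed reference outputs for the worked example (3-decimal precision;
## the copula fit's exact values land on .xxx5 in four cells, so the printed
## digits there are one rounding unit from either convention).
table_ipf_expected <- matrix(c(
  0.07, 0,    0,     0,     0,
  0.09, 0.04, 0,     0,     0,
  0,    0.13, 0.02,  0,     0,
  0,    0,    0.167, 0,     0.083,
  0,    0,    0.059, 0.211, 0,
  0,    0,    0.019, 0.014, 0.037,
  0,    0,    0.035, 0.025, 0
), nrow = 7, byrow = TRUE)

table_cbjf_expected <- matrix(c(
  0.063, 0.007, 0,     0,     0,
  0.073, 0.043, 0.013, 0.001, 0,
  0.022, 0.076, 0.050, 0.002, 0,
  0.002, 0.028, 0.142, 0.033, 0.045,
  0,     0.008, 0.047, 0.164, 0.051,
  0,     0.004, 0.022, 0.024, 0.020,
  0,     0.004, 0.025, 0.027, 0.004
), nrow = 7, byrow = TRUE)

## Random valid joint table; zero_frac controls the structural-zero share.
random_table <- function(m, n, seed, zero_frac = 0) {
  withr::with_seed(seed, {
    cells <- matrix(stats::rexp(m * n), m, n)
    if (zero_frac > 0) {
      k <- floor(zero_frac * m * n)
      if (k > 0) cells[sample.int(m * n, k)] <- 0
    }
    joint_table(cells / sum(cells))
  })
}

random_margin <- function(n, seed) {
  withr::with_seed(seed, {
    p <- stats::rexp(n) + 1e-3
    margin_vector(p / sum(p))
  })
}

## Independent O((mn)^2) Kendall enumeration: loop over ordered cell pairs.
kendall_brute <- function(tab) {
  B <- tab$cells; x <- tab$row_values; y <- tab$col_values
  m <- nrow(B); n <- ncol(B)
  tot <- 0
  for (i in 1:m) for (j in 1:n) for (k in 1:m) for (l in 1:n)
    tot <- tot + B[i, j] * B[k, l] * sign((x[i] - x[k]) * (y[j] - y[l]))
  tot
}
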