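# cbjf — copula-based joint fitting for synthetic populations

`cbjf` solves the **joint fitting problem** of synthetic population
generation: given a reference joint distribution of two ordinal attributes
(an `m × n` probability table **a**, or a micro-sample of survey records)
and new target marginal distributions **r**, **c**, construct a joint table
**b** that matches the target margins *exactly* while inheriting the
dependence structure of the reference.  It is aimed at epidemiological and
health-systems modellers who need baseline agent populations recalibrated
to forecast margins (an ageing population, a shifted severity mix) without
destroying the correlation between attributes.

## The method

The package's core is the **copula-based joint fit** (CBJF).  The discrete
joint CDF `A_ij = P[X ≤ x_i, Y ≤ y_j]` determines the copula of `(X, Y)`
uniquely at the marginal-CDF grid points `(u_i, v_j)`; bilinear
interpolation between them yields a genuine copula `C(u, v)` (uniform
margins, monotone, rectangle inequality).  Evaluating `C` at the cumulative
target margins `ũ_k = Σ_{i≤k} r_i`, `ṽ_l = Σ_{j≤l} c_j` and taking second
differences,

    b_kl = C(ũ_k, ṽ_l) − C(ũ_{k−1}, ṽ_l) − C(ũ_k, ṽ_{l−1}) + C(ũ_{k−1}, ṽ_{l−1}),

gives a fitted table whose margins equal the targets to machine precision,
with no iteration and no zero-cell pathology.  The same computation viewed
"from the reference side" distributes each mass `a_ij` over the overlapping
target rectangles of the unit square (`cbjf_distribute()`, sparse-friendly),
and applied per micro-record it yields a weighted resampling pool that
carries arbitrary extra attributes (`cbjf_resample()`; continuous margins
via the quantile transform `cbjf_continuous()`).

For comparison the package implements the classical baselines —
iterative proportional fitting (`ipf_fit()`, with convergence diagnostics
and a max-flow feasibility analysis of the zero-cell structure) and the
weighted least-squares / L1 optimization fits (`qp_fit()`, `lp_fit()`) —
plus a dependence-preservation evaluation suite: exact Pearson, Spearman
and Kendall measures on probability tables, a native MIC (maximal
information coefficient) implementation, and a synthetic benchmark
(`run_benchmark()`, `variation_sweep()`) with five reference joint families
and parametric marginal modification operators.

## Worked example

The built-in example is a 7 × 5 reference table with a staircase support
and shifted target margins:

```r
library(cbjf)
prob <- example_joint_problem()
b <- cbjf_fit(prob$a, prob$r, prob$c)
print(b, digits = 3)
#> joint_table: 7 x 5, total mass 1.000000000
#>       1     2     3     4     5
#> 1 0.062 0.008 0.000 0.000 0.000
#> 2 0.074 0.043 0.013 0.000 0.000
#> 3 0.022 0.076 0.050 0.002 0.000
#> 4 0.002 0.028 0.142 0.033 0.045
#> 5 0.000 0.008 0.047 0.164 0.050
#> 6 0.000 0.004 0.022 0.024 0.020
#> 7 0.000 0.004 0.025 0.027 0.004
fitting_error(b, prob$r, prob$c)
#> [1] 8.326673e-17
```

The margins match the targets exactly (the fitting error is the summed
maximum row- and column-margin deviation), and cells that are zero in the
reference — e.g. row 3, column 1 — have received probability mass: the
copula diffuses probability where the new margins require it.  IPF on the
same problem keeps every structural zero and needs an iterative sweep:

```r
fit <- ipf_fit(prob$a, prob$r, prob$c)   # tolerance 1e-5
fit$diagnostics
#> $iterations        100        (row+column sweep pairs)
#> $fitting_error     9.78e-06
#> $relative_entropy  0.0862     (minimal among margin-feasible tables)
#> $converged         TRUE
```

How well a fit preserves dependence is quantified by
`dependence_report()` (here with a deliberately coarse MIC sample for
speed):

```r
dependence_report(b, prob$a, mic_samples = 5000, seed = 1, jitter = FALSE)
#>               pearson spearman kendall   mic
#> observed        0.713    0.782   0.494 0.557
#> reference       0.753    0.834   0.531 0.674
#> abs_deviation   0.041    0.051   0.037 0.118
```

On the benchmark families at 100 bins (`run_benchmark()`), the copula fit's
summed absolute deviations are an order of magnitude below IPF's and the
QP's for every measure; see the methods vignette
(`vignettes/cbjf-methods.Rmd`) for the full experimental design and for the
regimes where the ranking reverses.

A command-line front end for shell pipelines ships in `inst/cli/cbjf`
(subcommands `fit`, `measure`, `resample`, `draw`, `benchmark`, `sweep`;
see `?cbjf_cli`).

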