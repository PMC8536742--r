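# pndecay

Sample-size-aware significance analysis: model the p-value of a two-sample
test as a function of the sample size, `p(n) = a·e^(−c·n)`, and decide
whether group differences are practically meaningful rather than merely
statistically detectable.

## Why

For large datasets (tens of thousands of observations per condition —
high-content imaging, flow cytometry, tracking experiments) null-hypothesis
significance testing degenerates: the p-value of any consistent test drifts
to zero as `n` grows whenever the distributions differ at all, so `p < 0.05`
stops discriminating between trivial and meaningful differences.

pndecay uses that very dependence as the measurement.  Monte Carlo
cross-validation (MCCV) repeatedly subsamples `n` observations from each
group (without replacement), tests each subsample pair (Mann–Whitney U by
default), and scans `n` over a log-spaced grid.  The resulting p-value cloud
is summarised by the exponential model

```
p(n) = a · exp(−c · n),   0 < a ≤ 1,  c ≥ 0
```

whose amplitude `a` and decay rate `c` behave like effect-size descriptors.
From the fit, the package derives a decision calculus:

| quantity | meaning |
|---|---|
| `n_gamma` | convergence point: smallest `n` with `|p'(n)| < gamma` |
| `delta` | signed area between the level `alpha` and `p(n)` over `[0, n_gamma]` |
| `theta` | binary decision index: 1 iff `delta ≥ 0` (plus degenerate-case rules) |
| `n_alpha`, `n_alpha_hat` | fitted / empirical minimum sample size for significance at `alpha` |
| `s_value` | Shannon information of a p-value, `−log2(p)` |

A flat curve at `a ≥ alpha` (no decay) yields `theta = 0` — the null
behaviour; `a < alpha` yields `theta = 1` at any `gamma`.  The convergence
threshold `gamma` (default `5e−6`) is constrained by `gamma ≤ 0.1` and
`gamma/c < alpha`.

## Worked example

Long-format input: one row per observation with a group label and a value.

```r
library(pndecay)
set.seed(2024)
df <- data.frame(
  group = rep(c("control", "treated"), each = 20000),
  value = c(rnorm(20000), rnorm(20000, 0.3)))   # a 0.3-sigma shift
write.csv(df, "example.csv", row.names = FALSE)

tab <- read_long_table("example.csv")
reports <- pairwise_compare(tab, seed = 7)
reports_to_table(reports)[, c("group_a", "group_b", "a", "c",
                              "n_alpha_int", "n_alpha_hat", "delta", "theta")]
#>   group_a group_b        a          c n_alpha_int n_alpha_hat    delta theta
#> 1 control treated 0.242287 0.01341855         117         131 6.107349     1
```

Reading: the fitted curve starts at `a ≈ 0.24` and decays at
`c ≈ 0.013` per observation; about 117 observations per group (empirically
131) suffice for significance at `alpha = 0.05`; the area distance is
positive, so `theta = 1` — with 20,000 observations per group this
0.3-sigma shift is a practically meaningful difference, not a sample-size
artifact.  For two groups drawn from the same distribution the same
pipeline returns a flat fit (`c ≈ 0`, `a ≈ 0.25` in the folded-tail
convention) and `theta = 0`.

The same analysis from a shell:

```sh
Rscript inst/cli/pndecay.R compare --input example.csv --out results --seed 7
Rscript inst/cli/pndecay.R simulate --mus 0,0.5,1 --seed 7   # synthetic study
Rscript inst/cli/pndecay.R robustness --mus 0,0.5,3 --repeats 10 --seed 7
```

Each run writes a flat CSV and a nested JSON report (full precision;
infinities as `"inf"`, undefined no-decay quantities as `"no_decay"`) and is
byte-identical when re-run with the same seed and configuration.

`run_study()` regenerates the synthetic validation design (N(0,1) against
shifted normals, 50,000 observations per group, grid of ~30 log-spaced sizes
on [2, 2500]); `robustness_rate()` reports how reproducible each decision is
under fresh samples and reduced budgets.  The methods vignette
(`vignettes/pvalue-size-decay.Rmd`) documents the model, the statistical
conventions (folded one-sided Mann–Whitney without continuity correction,
exact small-sample path, fit spaces) and the package's design choices.

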