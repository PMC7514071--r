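# impactsize

Non-parametric two-group effect size combining a median shift with a
distribution-shape difference.

## The problem

Difference-based effect sizes such as Cohen's d report an effect only when
the group centers move. In biomedical screening that misses a common and
diagnostically meaningful pattern: a marker whose distribution becomes
bimodal (or otherwise changes shape) under disease while its mean barely
moves — typical, for instance, of flow-cytometric surface-marker expression
in hematological malignancies. Cohen's d is also undefined whenever the
pooled standard deviation vanishes, which breaks automated feature ranking
on degenerate columns.

`impactsize` implements **Impact**, an effect size designed for exactly
this setting:

```
Impact(X1, X2) = w · DirCT · CTdiff + (1 − w) · DirMorph · MorphDiff
```

- `CTdiff = |median(X2) − median(X1)| / GMD(X1, X2)` — a non-parametric
  standardized location shift, normalized by the pooled Gini mean
  difference `GMD(ξ) = n⁻² Σᵢⱼ |ξᵢ − ξⱼ|` (rms-pooled across groups, with
  fallbacks that keep it positive even for constant groups);
- `MorphDiff = ∫ |pdf(X2) − pdf(X1)| dx ∈ [0, 2]` — the integrated
  absolute difference of the two estimated densities (Pareto density
  estimation by default, Gaussian KDE optional);
- `w = min(CTdiff, 2) / 2` — large location shifts saturate the weight, so
  the measure then behaves like a non-parametric Cohen's d;
- directions follow the ordering of the medians and of the mean
  log-modulus `sign(x)·log(|x|+1)` respectively;
- the result is gated to exactly **0** when a two-sample
  Kolmogorov–Smirnov test cannot reject that the groups are identical.

The measure is scale-invariant, antisymmetric under group swap, bounded by
2 when only the shape differs, and never NaN.

## Worked example

A unimodal control group against a mean-matched bimodal "patient" group —
the pattern a difference-based measure cannot see:

```r
library(impactsize)
set.seed(42)
cd79_like <- labeled_sample(
  rnorm(1000, 3.6, 0.7),                             # controls: unimodal
  c(rnorm(500, 2.9, 0.45), rnorm(500, 4.3, 0.45))    # patients: bimodal
)
impact(cd79_like)
#> Impact effect size
#>   impact     : -0.3973
#>   CTdiff     : 0.0052  (weight 0.003, direction +1)
#>   MorphDiff  : 0.3984  (direction -1, pde density)
#>   pooled GMD : 0.8834
#>   KS p-value : 4.54e-06  (n1 = 1000, n2 = 1000)

g <- split(cd79_like$value, cd79_like$group)
cohens_d(g[[1]], g[[2]])
#> [1] 0.0202
```

Cohen's d calls this a null effect (0.02); Impact reports a clear shape
effect (|Impact| ≈ 0.40, almost entirely MorphDiff — the medians are nearly
equal, so the location weight is 0.003). The sign of a pure shape effect
with matched centers is essentially arbitrary; use
`impact_config(absolute_value = TRUE)` when only the magnitude matters, and
`plot = TRUE` (or `plot_group_densities()`) to see the two densities.

All intermediate components (`ct_diff`, `morph_diff`, `gmd_pooled`,
`ct_weight`, directions, gate p-value) are returned, so the two effect
channels can be inspected separately.

## Synthetic benchmarks and experiments

Seeded generators reproduce the benchmark suites used to characterise the
measure: `make_dataset1()` (equal centers, different shapes),
`make_dataset2()` (degenerate/extreme cases), `make_dataset3_*_scan()`
(one component swept at a time), `make_dataset4()` (a 20-variable feature
matrix with noise, mean-shift and shape-shift blocks). On top of them,
`effect_size_table()` compares Impact with both Cohen's d pooling
variants, `robustness_subsampling()` measures estimator stability under
class-proportional subsampling, and `classification_experiment()` runs the
decision-tree / random-forest contrast (Monte-Carlo cross-validation, with
a permuted-training negative control).

A thin command-line wrapper is installed with the package
(`exec/impactsize`): `impactsize compute <file.csv>` writes a full JSON
report for a two-column table, `impactsize simulate --dataset 1..4` writes
the benchmark suites as CSV.

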