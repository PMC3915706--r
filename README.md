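# releaseopt

Robust parameter design for modified-release drug formulations from
replicated dissolution experiments.

A modified-release dosage form is engineered so the percent of drug
dissolved tracks a target profile: at each sampling time *t<sub>q</sub>*
the release should sit between a lower and upper specification limit,
ideally at a target *T<sub>q</sub>*. Formulation scientists control a few
factors (polymer levels, stirring speed, coating weight) and need the
settings whose profile is close to target *and* reproducible.
`releaseopt` turns a replicated dissolution design into those settings:

1. **Summary statistics** (`summarize_runs()`): per run and time point,
   the replicate mean, sample variance, coefficient of variation, and the
   covariance between time points across paired replicates.
2. **Response surfaces** (`fit_surfaces()`, `stepwise_select()`): each
   statistic is fitted by ordinary least squares,
   β̂ = (X′X)⁻¹X′y, over the full second-order polynomial in the linearly
   coded factors, with optional bidirectional stepwise screening
   (p-to-enter = p-to-remove = 0.05).
3. **Desirability optimization** (`build_composite()`, `solve_study()`):
   every fitted statistic is mapped to a Derringer–Suich desirability —
   nominal-the-best ramps for means around their LSL/target/USL,
   smaller-the-better for variance and CV, zero-target bands for
   covariances — and the weighted geometric mean
   D(x) = (∏ dᵢ(x)^wᵢ)^(1/Σwᵢ) is maximized over the coded factor box by
   a deterministic grid-plus-polish solver.

The competing criteria used in the field are included: the f1/f2
dissolution similarity factors (`f1_index()`, `f2_index()`) and the
mean-squared-error objective Σ(μ̂<sub>q</sub>(x) − T<sub>q</sub>)² +
Σv̂<sub>q</sub>(x) (`mse_objective()`). A synthetic experiment generator
(`synthetic_spec()`, `generate_experiment()`) supports end-to-end
validation, and six published formulation case studies ship as fixtures
(`load_example()`): diclofenac, terazosin, verapamil, metformin,
ranitidine, metoprolol.

## Worked example

Solve the diclofenac sodium case study — three factors (stirring speed,
CaCl₂ concentration, % liquid paraffin), three profile points (1, 6,
8 h), with mean, variance, CV and covariance surfaces:

```r
library(releaseopt)
res <- solve_example("diclofenac")
res
#> <optimization_result> maximum over 3 factor(s)
#> coded optimum:
#>      x1      x2      x3
#> -0.8258  0.7818  0.6233
#> decoded optimum:
#> # A tibble: 3 × 3
#>   name  unit  natural
#>   <chr> <chr>   <dbl>
#> 1 x1    rpm     587.
#> 2 x2    %        13.9
#> 3 x3    %        40.6
#> objective value: 0.536957 (grid: 0.536796)
#> component breakdown:
#> # A tibble: 12 × 5
#>    component kind    value desirability weight
#>    <chr>     <chr>   <dbl>        <dbl>  <dbl>
#>  1 mean_y1   NTB   36.5           0.346      1
#>  2 var_y1    STB   11.1           0.608      1
#>  3 cv_y1     STB    0.0698        0.446      1
#>  4 mean_y2   NTB   65.7           0.425      1
#>  ...
```

The coded optimum (−0.83, 0.78, 0.62) decodes to roughly 587 rpm, 13.9%
CaCl₂ and 40.6% liquid paraffin; the composite desirability 0.54 is the
geometric mean of the twelve component scores shown in the breakdown
(e.g. the fitted 1-hour mean of 36.5% against its 20/30/40 band scores
0.35). `sensitivity_sweep()` reports how this optimum moves when the
dispersion desirability bounds — a convention the source studies leave
unstated — are halved or doubled, and `autoplot(res)` draws the
one-factor-at-a-time desirability profiles. `tidy()` and `glance()`
methods return the optimum and fit summaries as tibbles.

Note that the reported optima printed in some source studies are not
reproducible from their own published surfaces (the 6-hour mean surface
evaluates above its upper specification limit at the study's reported
optimum); the package reports what the published coefficients actually
imply. See the methods vignette (`vignettes/dissolution-optimization.Rmd`)
for the full conventions and this analysis.

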