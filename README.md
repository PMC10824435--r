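# egmine — exceptional growth mining for on-farm longitudinal crop data

`egmine` finds interpretable subgroups of fields that grow *exceptionally*.
It is aimed at agronomists and data analysts working with on-farm
monitoring data: repeated in-season measurements of crop growth (e.g.
potato tuber weight in g m⁻², 5–7 sampling visits per field per season)
together with per-field descriptors (extractable soil nutrients, expert
dryness/nutrient classes, previous crop, nematodes, yield, irrigation,
planting date).

The analysis has three stages:

1. **Growth curves.** A year-stratified logistic nonlinear mixed model is
   fitted to all fields at once. For field *i* in year *k*,

   y<sub>ijk</sub> = exp(a<sub>ik</sub>) / (1 + exp(−b<sub>ik</sub>(t<sub>ijk</sub> − c<sub>ik</sub>))) · exp(e<sub>ijk</sub>),

   with a<sub>ik</sub> = α<sub>0k</sub> + σ<sub>a</sub>a<sub>i</sub>,
   b<sub>ik</sub> = exp(β<sub>0k</sub> + σ<sub>b</sub>b<sub>i</sub>),
   c<sub>ik</sub> = γ<sub>0k</sub> + σ<sub>c</sub>c<sub>i</sub>, and
   standardized random effects (a<sub>i</sub>, b<sub>i</sub>, c<sub>i</sub>)
   that are multivariate normal with unit variances and free correlations.
   The marginal likelihood is maximized with adaptive Gauss–Hermite
   quadrature (the random-effects integral is recentred per field at its
   posterior mode; one node = Laplace approximation).
2. **Targets.** Each field is summarized by its empirical-Bayes random
   effects: deviation in log maximum growth (*a*), steepness (*b*), and
   timing of half-maximum growth (*c*).
3. **Mining.** A beam search over conjunctions of descriptor conditions
   scores subgroups with the one-sample t statistic
   t<sub>G</sub> = μ̂<sub>G</sub>√n ⁄ σ̂<sub>G</sub> (sign chosen by the
   search direction), filters the candidates to the Pareto front over
   (directional mean, spread, size), and reports the top subgroups with
   confounder profiles (years, yield, irrigation, planting tertiles).

A seeded synthetic-farm generator with the exact statistical structure of
the model (including descriptor-linked "planted" subgroups) makes the
whole pipeline testable without any external data.

## Worked example

```r
library(egmine)

cfg <- default_farm_config(2024)                      # 4 years x 90 fields
cfg$planted_effects <- list(                          # ground truth to find:
  planted_effect("K_soil", "a", 0.8, prob = 0.75)     # high-K fields grow higher
)
sim <- simulate_farm(cfg)
sim$data
#> <egm_data>
#>   fields:       360
#>   observations: 2195 (time scale 34.94 days)
#>   descriptors:  15

fit <- fit_growth_model(sim$data, n_quadrature = 1)
glance(fit)
#> # A tibble: 1 x 6
#>   logLik r.squared n_fields n_obs n_quadrature converged
#>    <dbl>     <dbl>    <int> <int>        <dbl> <lgl>
#> 1  -340.     0.966      360  2195            1 TRUE

round(random_effect_correlations(fit), 2)
#>       a     b     c
#> a  1.00 -0.65  0.52
#> b -0.65  1.00 -0.84
#> c  0.52 -0.84  1.00

egm_report(fit, sim$data, target = "a", direction = "high")
#>                                   description   n  mean    sd quality mean_yield
#> 1         K_soil <= 497.1833 & K_soil > 327.4  50 0.619 0.830    5.27       59.7
#> 2         K_soil > 327.4 & Mn_soil <= 3220.55  30 0.796 0.912    4.78       61.3
#> 3        Dryness != 'dry' & K_soil > 248.5667 100 0.446 0.933    4.78       57.0
#> 4 K_soil > 327.4 & Nutrient_content != 'poor'  37 0.677 0.883    4.66       60.1
#> 5       K_soil > 248.5667 & Mg_soil <= 253.65 100 0.425 0.932    4.56       55.2
```

Reading the output: the model explains 96.6% of the variance in observed
weights (`r.squared`); steepness is strongly negatively correlated with
both the maximum and the midpoint, as expected for s-shaped growth. The
mined top-5 for "exceptionally high maximum growth" recovers the planted
condition — every report line involves a high-potassium condition near
the planted threshold (the 75th percentile of `K_soil`, here ≈ 327
kg ha⁻¹), with subgroup means of the *a* effect around +0.4 to +0.8
standard deviations and correspondingly high mean yields.

Real data enter through two CSV files (one growth row per sampling
event, one descriptor row per field-year):

```r
d   <- load_dataset("growth.csv", "fields.csv")
fit <- fit_growth_model(d)                 # 5^3-node adaptive quadrature
sg  <- mine_subgroups(d, fit, target = "b", direction = "low")
top <- top_k_report(pareto_front(sg))
profile_subgroups(top, d)
```

`autoplot(fit, data)` draws observed points against fitted field curves;
`plot_pareto(sg)` shows the mined subgroups in the Pareto space. A thin
command-line interface over the same functions is included at
`inst/cli/egm.R` (`validate`, `simulate`, `fit`, `mine`, `report`).

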