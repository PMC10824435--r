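---
title: "Exceptional growth mining: model, search, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exceptional growth mining: model, search, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egmine)
```

## The problem

On a farm that cultivates many small fields, crop growth varies strongly
from field to field, and the reasons are heterogeneous: several soil and
management conditions can depress or boost growth simultaneously in
different subsets of fields. A single whole-farm model averages these
stories away. `egmine` takes the opposite route: it first summarizes each
field's seasonal growth by three interpretable curve parameters, then
*searches* for small, describable subgroups of fields whose parameters
deviate systematically from the farm average.

The package was built around potato tuber growth monitored by repeated
in-season plant samples (5–7 visits per field, tuber weight converted to
g m⁻²), with each field characterized by extractable soil nutrients
(N, P, K, Ca, Mg, S in kg ha⁻¹; B, Fe, Mn, Zn in g ha⁻¹), expert
categories (dryness, nutrient content), previous crop, nematode presence,
yield, irrigation, and planting date. Nothing in the code is specific to
potatoes: any longitudinal, roughly s-shaped growth response with
per-unit descriptors fits.

## The growth model

Tuber weight on field $i$ at standardized day $t_{ijk}$ of year $k$ is
modelled as a logistic curve with multiplicative lognormal error:

$$y_{ijk} = \frac{\exp(a_{ik})}{1 + \exp\{-b_{ik}(t_{ijk} - c_{ik})\}}
  \exp(e_{ijk}), \qquad e_{ijk} \sim N(0, \sigma^2)$$

with field-level parameters built from year-specific fixed effects and
standardized field random effects:

$$a_{ik} = \alpha_{0k} + \sigma_a a_i, \qquad
  b_{ik} = \exp(\beta_{0k} + \sigma_b b_i), \qquad
  c_{ik} = \gamma_{0k} + \sigma_c c_i,$$

$$(a_i, b_i, c_i) \sim N(0, R), \qquad
  R = \begin{pmatrix} 1 & \rho_{ab} & \rho_{ac} \\
  \rho_{ab} & 1 & \rho_{bc} \\ \rho_{ac} & \rho_{bc} & 1 \end{pmatrix}.$$

`a` is the field's deviation in log maximum growth, `b` in steepness, and
`c` in the timing of half-maximum growth. The random-effect variances are
shared across years; exponentiation keeps the steepness and the midpoint
scale positive. Days after planting are divided by their pooled standard
deviation before fitting, purely for numerical conditioning; `tidy(fit,
scale = "days")` converts steepness and midpoint terms back to days.

Two modelling conventions are worth spelling out:

* The conditional likelihood is evaluated as a normal density on
  *log* weight. This is algebraically identical to the multiplicative
  lognormal error above and avoids overflow for large asymptotes.
* Weights recorded as exactly zero (fields destroyed by extreme weather)
  cannot carry a multiplicative error; `egm_data()` sets them aside from
  the likelihood-ready observations and reports them, consistent with a
  missingness mechanism that is at worst missing-at-random. They are
  never silently dropped: the assembly report accounts for every input
  row as accepted, excluded-zero, or rejected (no matching field record).

## Estimation

The marginal likelihood integrates the three correlated random effects
out of each field's contribution. `marginal_loglik()` does this with
*adaptive Gauss–Hermite quadrature*: for every field the integrand is
recentred at the posterior mode of $(a_i, b_i, c_i)$ and rescaled by the
curvature there, then evaluated on an $m^3$ tensor grid ($m$ =
`n_quadrature`, default 5, i.e. 125 nodes; $m = 1$ is the Laplace
approximation). The posterior modes are found by a damped Newton
iteration, vectorized across all fields, using the Gauss–Newton
approximation to the Hessian — positive definite by construction, which
keeps both the Newton step and the quadrature scaling stable. The same
modes are the empirical-Bayes estimates that later become mining targets.

`fit_growth_model()` maximizes the marginal likelihood with BFGS.
Unconstrained parameterizations are used throughout: log scales for
$\sigma_a, \sigma_b, \sigma_c, \sigma$, and a spherical
(Cholesky-angle) parameterization of $R$, so every optimizer candidate is
a valid positive-definite correlation matrix. Starting values come from
per-year least-squares fits of the fixed-effect logistic on pooled log
weights, with scales started at 0.3 and correlations at 0. When
`n_quadrature > 1`, the optimizer first converges under the cheap Laplace
approximation and then refines under full quadrature; on the simulated
farm designs below the two stages differ only in the third decimal of the
parameters, but the refinement is kept because the quadrature constant
matters when comparing likelihoods across quadrature settings.

Fit quality is summarized, deliberately simply, by the $R^2$ of an
ordinary regression of observed weights on the empirical-Bayes predicted
weights on the original g m⁻² scale.

Numerical edge cases: log steepness is capped at 30 (beyond that the
curve is numerically a step and the linear predictor would produce
`Inf * 0`); Newton steps are trust-region-limited to length 4 on the
standardized random-effect scale; fields whose Gauss–Newton Hessian is
near-singular fall back to damped steps with per-field backtracking.
Degenerate inputs (all weights equal, a single distinct sampling day,
non-positive-definite correlation guesses) raise errors rather than
producing silent nonsense.

## From curves to subgroup mining

After fitting, each field is reduced to its empirical-Bayes triple
$(a_i, b_i, c_i)$. Under the population model each component is a sample
from a zero-mean distribution, so a subgroup $G$ of $n$ fields whose
component mean $\hat\mu_G$ is far from zero is *exceptional*. The
quality measure is the one-sample t statistic

$$t_G = \frac{\hat\mu_G \sqrt{n}}{\hat\sigma_G},$$

signed by the search direction: $\varphi_{high} = t_G$ for positive
shifts, $\varphi_{low} = -t_G$ for negative ones. The statistic is
scale-free, and mining the negated targets in the opposite direction
gives identical results — both properties are tested.

Subgroups are *descriptions*: conjunctions of conditions on the field
descriptors, e.g. `K_soil > 308.1 & Dryness != 'wet'`. Numeric
descriptors contribute `<=`/`>` conditions at the equal-frequency
quantile thresholds of the *current* subgroup (`n_bins = 6`, i.e. 5
thresholds, recomputed at every refinement level — dynamic
discretization); categorical descriptors contribute `==`/`!=` conditions
per observed level. `beam_search()` explores this language level-wise to
depth `d`, carrying the `w` best candidates (default `beam_width = 25`)
to the next level. Descriptions are kept canonical (at most one `<=` and
one `>` per numeric attribute, tightest bound kept), candidates are
deduplicated on (canonical description, member set), records missing a
condition's attribute never satisfy the condition, and ties are broken
deterministically: higher quality, then shorter description, then
lexicographic order. `beam_width = Inf` turns the search exhaustive,
which the test suite exploits as an oracle.

During the search the only size constraint is the statistical minimum
(`min_size = 2`, and zero-spread subgroups score $-\infty$); the
reporting filter is deliberately separate, so that the Pareto stage can
still trade small subgroups off against large ones.

## Pareto filtering and reporting

A mined list is typically long and redundant. `pareto_front()` keeps the
subgroups not dominated in the three-objective space (directional mean —
higher better, standard deviation — lower better, size — higher better).
The mean objective is oriented by the search direction (negated for
low-direction runs), since desirability is defined by the sign of the
quality measure. Equal triples do not dominate each other, and both are
kept. The filtering is asymmetric by nature: it discards candidates known
to be dominated, but cannot certify optimality of what remains, because
only subgroups the beam search visited are compared.

`top_k_report()` then mirrors how results are presented: subgroups with
$n \le 15$ are dropped, redundant same-attribute conditions inside one
description are collapsed to the tightest threshold, nested subgroups
whose descriptions differ only in thresholds on the same attributes are
represented by the larger one, and the `k = 5` best survivors are
returned. `profile_subgroups()` appends the confounder summaries
inspected alongside each subgroup: year distribution (the targets are
within-year deviations, so a subgroup concentrated in one year would
suggest a weather story), mean yield, irrigation counts, and per-year
planting-period tertiles (stable date sort; remainders go to the earlier
tertiles; missing dates are labelled unknown and excluded from counts).
These are descriptive only — no test is attached, and none of this is a
causal analysis.

## The synthetic farm generator

`simulate_farm()` exists so that every stage is testable end-to-end
without any external data. It draws correlated standardized random
effects, builds per-field logistic curves from year-specific fixed
effects, samples 5–7 distinct visit days per field uniformly in the
season window, applies multiplicative lognormal error, and generates
descriptors (lognormal soil nutrients, three-level expert categories),
yields linked to the `a` effect, irrigation flags, and planting dates.
Ground truth is always returned next to the data, never hidden.

`default_farm_config()` fixes the study conditions used by the
recovery checks: 4 years × 90 fields, asymptotes between roughly 3000
and 8000 g m⁻², per-year mean yields between 38 and 63.5 ton ha⁻¹,
measurement error 0.15 on the log scale, and random-effect correlations
$(\rho_{ab}, \rho_{ac}, \rho_{bc}) = (-0.65, 0.49, -0.73)$: strong
negative coupling of steepness with both the maximum and the midpoint,
and a weak positive association between maximum and midpoint, as
observed for potato tuber growth. Note that the two strong negative
correlations *force* the third to be positive — the triple with all
three negative at these magnitudes is not a valid correlation matrix —
so the weak positive sign is a matter of internal consistency, not
taste. `planted_effect()` adds descriptor-linked shifts (for instance
$+0.8$ on the `a` mean for fields in the top quarter of `K_soil`),
which is how the mining stage's sensitivity is measured.

What the generator does *not* emulate: spatial correlation between
neighbouring fields, year-by-descriptor interactions, weather covariates,
measurement-protocol drift, and the occasional destroyed-field zero
weights of real monitoring data. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation and
search machinery under the stated model, not robustness to every way
real farm data can violate it.

## Problem sizes and numerical tolerances used in the checks

The package's own acceptance checks (see `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`) run at these sizes, chosen to be
comfortably informative for each quantity:

* quality-measure consistency: the 30 published case-study subgroup
  rows; printed inputs are rounded to two decimals, so agreement is
  expected to about ±0.1 on the quality value;
* oracle equivalences: a 12-record, 3-descriptor fixture for exhaustive
  search; 100 random triples for Pareto dominance; a 2-field, 14-visit
  toy with 10⁶ Monte-Carlo prior draws for the quadrature (agreement
  within 3 Monte-Carlo standard errors);
* parameter recovery: one full fit of the 360-field default design with
  5-point quadrature — correlations recovered within ±0.10, scales
  within 15%, regression $R^2$ between 0.85 and 0.97;
* planted-subgroup recovery: ten seeded repetitions of
  simulate → fit (Laplace) → mine, requiring the planted attribute in
  the top-3 descriptions in at least 90% of runs. The Laplace
  approximation is used for these repeated fits; it agrees with 9-point
  quadrature to well under 1% of the log likelihood on the toy fixture,
  and the empirical-Bayes modes it produces are identical by
  construction.

## Known limitations

* Only the logistic curve family is implemented; crops whose response
  rises and then declines (e.g. haulm weight) need a different mean
  function.
* Zero weights are excluded, not modelled; a censoring component would
  be needed to use them as information.
* The search's numeric thresholds depend on the binning choice
  (`n_bins`) and, mildly, on the beam width; exact threshold values in
  reports should be read as representatives of a neighbourhood, not
  sharp biological cutoffs.
* Empirical-Bayes estimates are shrunken; subgroup means on the EB scale
  understate the true latent shifts, which is conservative for
  discovery but matters if effect sizes are interpreted literally.
* Subgroup discovery is exploratory: overlapping subgroups, collinear
  descriptors (e.g. K and Ca), and confounding by management all mean
  that descriptions generate hypotheses rather than causal claims.
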