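---
title: "Methods: cause-of-death estimation for ages 5-19"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cause-of-death estimation for ages 5-19}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the model, the integration algebra, the choices made where the design was
genuinely open, and what the validation suite does and does not establish.

## The estimation problem

Deaths at ages 5–19 are distributed over roughly fifteen to twenty causes,
but the data available to estimate that distribution are heterogeneous and
sparse. A minority of countries have high-quality vital registration
(HQVR), whose observed cause distributions can be used directly. The rest
must be modelled from whatever multi-cause death-count studies exist —
typically verbal autopsy studies with median sizes of a few hundred deaths,
available for only a subset of countries — and the modelled fractions must
then be reconciled with three external constraints: all-cause mortality
envelopes (the total deaths per country-year-group are fixed externally),
single-cause programme estimates (HIV/AIDS, tuberculosis, measles, crisis
deaths, each with its own uncertainty interval), and structural
epidemiological rules (malaria at these ages cannot plausibly exceed its
under-5 share and is absent above age 14).

Estimation is stratified four ways by age and sex (5–9, 10–14, 15–19
female, 15–19 male), each stratum with its own cause list: maternal causes
appear only in 15–19 females, congenital disorders and measles only in
5–9, cardiovascular disease, self-harm and interpersonal violence only in
the 15–19 groups. The 15–19 cause lists carry no separate
lower-respiratory-infection (LRI) cause — LRI deaths at those ages sit
inside "other CMPN" — which is why the modelled cause count is 11 in
15–19-year-old females and 10 in males (the difference is the maternal
cause), and why the tuberculosis carve-out routes both TB components into
other CMPN in those groups but splits pulmonary TB into LRI below age 15.
Countries without HQVR are split at a probability of death between ages 5
and 19 of 10 per 1000 into low-mortality (LMM) and high-mortality (HMM)
modelled strata, fitted separately; the boundary value itself is assigned
to HMM, an arbitrary but deterministic tie rule.

## The Bayesian LASSO multinomial-logistic model

For study $i$ in country $j$ with $n_i$ total deaths over modelled causes
$c = 1, \dots, C$ (reference cause first):

$$
y_i \sim \mathrm{Multinomial}(n_i, p_i), \qquad
p_{ic} = \frac{\exp \eta_{ic}}{\sum_k \exp \eta_{ik}}, \qquad
\eta_{ic} = \beta_{0c} + x_i^\top \beta_c + u_{jc},
$$

with $\eta \equiv 0$ for the reference cause ("other CMPN", which is
modelled and present in every group). Priors:

* $\beta_{cp} \sim \mathrm{DoubleExponential}(0, \lambda)$ — the Bayesian
  LASSO. The penalty $\lambda$ is the rate of the Laplace prior; larger
  values shrink covariate effects toward zero. Intercepts are excluded
  from the penalty and given weakly informative Normal(0, 10²) priors,
  standard practice for shrinkage models. The exact hyper-parameterisation
  of the original analysis is not published, so this parameterisation is
  the package's documented interpretation of "a LASSO penalty on the model
  coefficients"; $\lambda$ has no hyperprior and is chosen by
  cross-validation instead.
* $u_{jc} \sim \mathrm{Normal}(0, \sigma_u)$ with $\sigma_u = 0.07$,
  fixed, for countries contributing studies (elsewhere $u = 0$ at
  prediction time). Fixing rather than estimating $\sigma_u$ matches the
  out-of-sample protocol under which the penalty is selected; it is a
  configurable argument.

Covariates are standardised on the training studies and the transform is
stored, so the prediction panel is mapped through the identical scale. The
model is expressed in JAGS (the double-exponential prior is native there)
and sampled with fixed per-chain seeds, making fits bit-reproducible for a
given seed and chain count. Convergence is monitored by split-chain
$\hat R$ on every parameter; values above 1.1 raise a warning rather than
an error, because a long pipeline run should record and flag a marginal
fit, not die.

### Penalty selection

$\lambda$ minimises mean out-of-fold RMSE between posterior-mean predicted
fractions and observed study fractions, over study-level folds stratified
by country (never row-level folds, which would leak a study's own counts
across the split). Held-out studies from countries absent from the
training split are predicted with $u = 0$. RMSE cells are unweighted — the
published description does not state a weighting, and unweighted cells
treat a 30-death study and a 3000-death study as equally informative about
model fit, which is conservative for the small-study regime this model
lives in. Ties are broken toward the larger penalty (more shrinkage). The
default fold count is 5: under the default validation scenario (12
study-contributing countries, 4 studies each) 5 folds keep several studies
of each country in every training split; the fold count is an argument.

## Integration algebra

Per country-year-group cell, per posterior draw, in this order:

1. **Malaria**: fraction capped at the under-5 malaria fraction for that
   country-year (zero where incidence is zero), excess redistributed pro
   rata over the remaining causes. Capping before squeezing reflects the
   cap's role as a constraint on the *modelled* fraction; the stage order
   is an explicit argument of the cell-level functions, since the
   published account fixes the cap as post-hoc to modelling but not its
   order relative to squeezing.
2. **Other-CMPN squeeze**: HIV, endemic measles and extrapulmonary TB
   fractions (death draws over envelope deaths, truncated to [0, 1]) are
   carved out of the modelled other-CMPN fraction. The residual floor —
   the median other-CMPN fraction across HQVR country-years — is held
   fixed: when the single causes exceed the available room they are scaled
   down pro rata, and the floor is never eaten into. The alternative
   reading (scaling the residual along with the single causes) is not
   implemented; holding the floor fixed preserves the floor's motivation
   as a minimum attainable fraction.
3. **LRI squeeze**: pulmonary TB into modelled LRI with the residual LRI
   floor, in the 5–9 and 10–14 groups. Reported tuberculosis is the sum of
   the two squeezed components.
4. **Crisis**: the raw crisis fraction is capped at the country-year's
   maximum plausible fraction; existing mass is scaled by $(1-f)$ and $f$
   is added to the cause matching the crisis nature (collective violence
   and natural disasters map to their own causes; epidemics map to measles
   where the group has it, else other CMPN — the nature-to-cause map is a
   user-supplied argument, since the original redistribution table is not
   published). Crises outside the envelope add deaths on top: the envelope
   is inflated by $1 + f$ and the fraction re-expressed on the inflated
   scale, so the supplied crisis deaths are recovered exactly.

Every partition sums exactly to its modelled composite (checked to 1e-12
against an independently coded oracle on 10 000 random simplexes), and the
full chain preserves the simplex to 1e-9 per draw.

Degenerate inputs: a composite entirely consumed by its own cause (all
malaria, cap < 1, nothing to redistribute to) spreads the excess uniformly,
since pro-rata ratios are undefined at zero; a zero envelope with zero
cause deaths yields zero fractions; a zero envelope with nonzero
single-cause deaths is an error, not a silent truncation.

## Uncertainty propagation

Draw $k$ of every output uses draw $k$ of every input: posterior draws of
the modelled fractions, envelope draws (recycled if fewer than the
posterior draws), and single-cause draws sampled from their 95% intervals
— a lognormal quantile-matched to the bounds when the lower bound is
positive (recentred multiplicatively so the draw median equals the point
estimate, preserving lower ≤ point ≤ upper), and a zero-truncated normal
otherwise. Points are medians of draws and intervals the 2.5–97.5
percentiles, so the point always lies inside its interval — the reason
medians were chosen over means. Aggregation sums deaths per draw across
countries; regional rates divide summed deaths by summed person-years
(recovered per draw as deaths/rate), so regional fractions are exactly the
death-weighted means of country fractions. Trend summaries use
$\mathrm{AARR} = 100 \cdot \ln(r_{t_1}/r_{t_2})/(t_2 - t_1)$ computed per
draw on rates (not counts), the standard log formulation; natural
disasters are excluded from AARR tables because single-year catastrophes
make the two-endpoint contrast meaningless.

## The synthetic-data generator

`make_truth()` and its companions generate all five input streams from a
known truth: a sparse multinomial-logistic surface over AR(1) covariates
(autocorrelation 0.9, mimicking slowly varying country indicators),
country random effects with SD 0.07, log-linearly declining envelopes with
lognormal draw noise, single-cause fraction surfaces converted to death
series with ±20% intervals, and malaria/crisis constraints. The default
conditions mirror the data-scarcity regime the model is built for: 30
countries of which 12 contribute studies, 4 studies per country, study
sizes Poisson with mean 185 deaths (the average study size reported for
the worst-covered age-sex group), 20 years. Stress cases are engineered
deliberately: one country whose HIV and extrapulmonary-TB fractions exceed
the room in its modelled composite (exercising the pro-rata squeeze), one
country with a binding malaria cap, two with zero malaria incidence, and
one crisis with a raw fraction of 0.9 against a cap of 0.3.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: real covariates with meaningful semantics
(and their measurement error), misclassified causes in verbal autopsy
studies, non-representative study placement, garbage-code and completeness
adjustments upstream of the inputs, or correlation between envelope errors
and CSMF errors. The validation demonstrates that the machinery recovers a
truth of the assumed form from data of the assumed sparsity, not that the
assumed form is right.

`true_full_csmf()` composes the generator's full-cause truth using the
same deterministic squeeze algebra the pipeline applies (with the truth's
own single-cause fractions and caps). That algebra is verified separately
against a brute-force oracle, so its reuse in the truth composition does
not mask arithmetic errors; what the recovery tests then isolate is the
statistical estimation.

## Validation problem sizes

The shipped validation suite runs the model at deliberately reduced sizes,
chosen as the smallest problems that still exercise every code path:
scenario fixtures of 6–12 countries over 10 years with 80–100 envelope
draws; MCMC at 1–2 chains with 150–400 kept iterations; parameter-recovery
over 20 replicates (P = 2, half the effects zero); interval-calibration
over 200 replicates of an intercept-only scenario (the covariate model's
calibration is covered by the recovery replicates); penalty selection on a
3-point grid with 3 folds. Package defaults remain at analysis scale
(4 chains × 1000/1000, 1000 draws, 10-fold-capable folds argument).
The acceptance script reports, at matching sizes: mean absolute CSMF error
against truth ≈ 0.005, per-draw death-conservation error ≈ 1e-12, and 95%
interval coverage ≈ 95–97%.

## Known limitations

* Separate per-stratum fits borrow the other stratum's model when a
  stratum has no studies, rather than model-averaging across strata
  (averaging was considered and rejected upstream as unstable).
* The residual floors are medians over HQVR country-years, computed once
  per group; they do not vary by year or region.
* Multi-country pooled studies are treated as single-country records at
  their period midpoint; the covariate row is evaluated at that midpoint.
* HQVR pass-through uses observed fractions as-is; any within-country
  sampling noise in the vital registration counts is not propagated
  (envelope uncertainty still is).
* Draw-based quantile intervals inherit Monte Carlo error of order
  $1/\sqrt{K}$; K defaults to 1000 and is an argument everywhere.
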