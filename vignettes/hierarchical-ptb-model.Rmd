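---
title: "Modelling preterm-birth risk by education, nativity, and Hispanic subgroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling preterm-birth risk by education, nativity, and Hispanic subgroup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

`ptbhier` estimates the absolute risk of preterm birth (PTB, delivery before
37 completed weeks) as a function of completed years of maternal education
(0–17), jointly stratified by Hispanic subgroup (Mexican, Puerto Rican,
Cuban, Dominican, Central American, South American, Other/Unknown) and
maternal nativity (US-born vs foreign-born; for Puerto Ricans,
mainland-born vs island-born). With 7 × 2 strata and 18 education levels,
saturated stratum-specific estimates would be hopelessly noisy in the small
strata (US-born Cubans, foreign-born Cubans), while a single pooled
dose-response would erase exactly the heterogeneity of interest. The model
therefore partially pools: each stratum gets its own dose-response curve,
but curves borrow strength across ethnic groups *within* a nativity class,
with the amount of borrowing estimated from the data.

## The model

For birth $i$ in ethnic group $j = 1,\dots,7$ and nativity class
$k \in \{0, 1\}$:

$$
Y_{ijk} \sim \mathrm{Bernoulli}(p_{ijk}), \qquad
\mathrm{logit}\, p_{ijk} = \delta_{jk}
  + \sum_{g=1}^{3} \alpha_{gjk}\, q_g(e_{ijk})
  + \sum_m \beta_m x_{mijk},
$$

where $e$ is education in years, $q_1, q_2, q_3$ are restricted quadratic
spline terms (below), and $x_m$ are covariate indicators. The hierarchical
layer shrinks each stratum's intercept and spline coefficients toward a
nativity-class mean:

$$
\delta_{jk} \sim N(\mu_{0k},\, 1/\tau_0), \qquad
\alpha_{gjk} \sim N(\mu_{gk},\, 1/\tau_g), \qquad g = 1, 2, 3,
$$

with hyperpriors $\mu_{gk} \sim N(0, 1)$,
$\tau_g \sim \mathrm{Gamma}(0.1,\, 0.1)$ (shape, rate), and
$\beta_m \sim N(0, 10)$. Ethnic groups are exchangeable within a nativity
class; no pooling crosses nativity classes, because the means $\mu_{gk}$ are
per-class. A large $\tau_g$ means the data found the strata homogeneous and
shrinkage is strong; heterogeneity drives $\tau_g$ down and the curves
apart. By default each $\tau_g$ is shared across the two nativity classes —
four precision terms in total, the literal reading of $\tau_0,\dots,\tau_3$ —
and `model_spec(tau_structure = "per_nativity")` provides the variant with
nativity-specific precisions $\tau_{gk}$, since the descriptive prose about
borrowing "for foreign born mothers" admits that reading too.

The priors are deliberately weakly informative. At the cohort sizes the
model is meant for (tens to hundreds of thousands of births) the likelihood
dominates; the prior-sensitivity harness in the test suite checks that the
prior is recovered exactly when the likelihood is switched off
(`sample_posterior(..., prior_only = TRUE)`), which exercises every
conditional distribution the sampler uses.

## The restricted quadratic spline

Education enters through three basis columns with knots $k_1 < k_2 < k_3$
(default 8, 11, 13 years):

$$
q_1(e) = e, \qquad
q_2(e) = (e - k_1)_+^2 - (e - k_3)_+^2, \qquad
q_3(e) = (e - k_2)_+^2 - (e - k_3)_+^2 .
$$

Subtracting the outer-knot plus-function cancels the quadratic growth above
$k_3$, so the curve is quadratic on $[k_1, k_3]$, exactly linear below
$k_1$ and above $k_3$, and continuously differentiable everywhere. This is
the standard construction that enforces linear tails with exactly three
coefficients; whether the original analysis ordered its three columns the
same way is unknowable from the text, but any ordering spans the same
function space. The linear-tail and $C^1$ properties are property-tested
over random coefficients.

The columns are centred at the fitting sample's means (`center_basis()`)
before sampling. Centring is a pure reparameterisation — fitted
probabilities are unchanged — but it removes most of the posterior
correlation between $\delta_{jk}$ and the spline coefficients and
noticeably improves mixing. The centring offsets are stored with the fit so
that risk can be evaluated at any education value on a consistent scale.

## Posterior computation

The sampler is Gibbs throughout, using Pólya-Gamma data augmentation for
the logistic likelihood: given latent $\omega \sim \mathrm{PG}$ variables,
every coefficient block has a Gaussian full conditional, and the
hierarchical means and precisions have normal/gamma conjugate updates.
Three implementation choices matter:

* **Cell collapsing.** The Bernoulli records are aggregated to binomial
  counts over unique design cells (stratum × education × covariate
  pattern). The sum of $n$ independent $\mathrm{PG}(1, z)$ variables is
  $\mathrm{PG}(n, z)$, so one augmentation draw serves a whole cell. For an
  age-adjusted fit the cell count is bounded by
  $14 \times 18 \times 5 = 1260$ regardless of cohort size, which is what
  makes full-scale fits cheap; fully-adjusted fits collapse less and scale
  with the number of distinct covariate patterns.
* **PG sampling.** $\mathrm{PG}(1, z)$ is drawn exactly with Devroye's
  alternating-series rejection sampler (compiled code, driven by R's RNG so
  `set.seed()` reproducibility holds). Integer shapes up to 30 are sums of
  exact draws; larger shapes use a moment-matched normal approximation,
  whose relative error at those counts is far below Monte Carlo noise (the
  test suite compares the two paths directly).
* **Blocking.** Each stratum's $(\delta_{jk}, \alpha_{1jk}, \alpha_{2jk},
  \alpha_{3jk})$ is drawn jointly from its 4-dimensional Gaussian
  conditional, then $\beta$ jointly, then $(\mu, \tau)$. Joint
  stratum blocks avoid the slow mixing a scalar Gibbs scan would have on
  correlated spline coefficients.

Default run settings are desk-scale: 4 chains × 6,000 iterations, 1,000
burn-in, thinning 5, dispersed random starting states, chain $c$ seeded as
`seed + c - 1`. Production-scale settings (10^6 iterations, 10^4 burn-in,
thin 10) are a `mcmc_config()` call away but are unnecessary for the Gibbs
sampler's mixing at these dimensions; split-$\widehat R$ and effective
sample size (`diagnostics()`) quantify what trace plots show. Numerical
guards: log-odds are clipped at ±30 before the inverse-logit (probabilities
within 10⁻¹³ of the boundary), and the sampler aborts with a diagnostic on
any non-finite state.

## Posterior summaries

All deliverables are computed draw by draw and summarised afterwards:
absolute risk surfaces $\mathrm{expit}(\delta_{jk} + \alpha_{jk}'(q(e) -
\bar q) + \beta' x_{\mathrm{ref}})$ per retained draw, then means, medians
and central 95% intervals; risk differences (US-born minus foreign-born at
the same education) formed within draws before summarising. Summarising
parameters first and transforming after would bias every nonlinear
functional — a dedicated test constructs skewed draws where the two orders
visibly disagree.

The reference covariate pattern defaults to the lowest-risk levels (age
20–24, female infant, parity 1–4, adequate prenatal care, no tobacco,
alcohol, or medical-risk conditions), so the reported risks are best-case
absolute risks and the fitted intercept is directly interpretable.
Age-adjusted fits evaluate at age 20–24 only. Risk differences are reported
from 8 years of education upward, and native-born surface rows below 8
years are flagged (`below_floor`) and suppressed in figures rather than in
estimation: educational attainment below 8 years is vanishingly rare among
US-born mothers, so those grid points are prior-driven extrapolation.

## The synthetic registry

No individual-level vital-statistics file can be redistributed, so the
package ships a generator (`generate_registry()`) whose preset
(`make_table1_preset()`) reproduces the published descriptive structure of
the study population: the 14 stratum sizes exactly; education distributions
as discretised truncated normals on 0–17 whose *post-discretisation* mean
and SD are moment-matched to the published values (matching the latent
normal instead would bias low-education strata — the foreign-born Mexican
stratum sits close enough to the 0 truncation for that to matter at its
sample size); stratum-level covariate prevalences (% aged 35+, % adequate
prenatal care, % smoking, % drinking) as published; and stratum intercepts
solved by one-dimensional root finding so that the *marginal*,
covariate-averaged PTB probability equals the published preterm percentage
— the published rates are marginal rates, not reference-pattern rates, so
calibrating the intercept directly to them would be wrong without the
averaging step, which is done by exact enumeration of the covariate cell
distribution rather than simulation.

Quantities the descriptive table does not report were fixed once at values
typical of US urban natality files and are documented in
`default_shared_prevalences()` and `default_covariate_effects()`: the
35–39/40+ split within the 35+ group (78/22), the under-35 age split
(38/34/28), parity distribution (42% nulliparous, 53% with 1–4, 5% with
5+), intermediate/inadequate split of non-adequate prenatal care (62/38),
51.2% male infants, eight medical-risk conditions with prevalences between
0.1% (eclampsia) and 3% (hypertension, diabetes), and positive covariate
log-odds effects between 0.05 (age 25–29) and 0.90 (medical-risk
dichotomy) so that the reference pattern is genuinely lowest-risk.

The generating dose-response is a known restricted quadratic spline per
stratum: native-born strata (and island-born Puerto Ricans, matching the
published finding that they behave like the native-born) decline steeply
above the knot span (−0.11 log-odds per year), other foreign-born strata
are much flatter (−0.035 per year) with a shallow maximum near 10–12
years. `true_risk()` returns the exact generating probability at any
(stratum, education, covariate pattern), and
`true_age_adjusted_risk()` returns the truth marginalised over the non-age
covariates — the correct oracle for age-adjusted fits, whose reference risk
targets that marginal quantity rather than the all-reference-pattern risk.

Contamination records (non-Hispanic, under-20, multiple births; 2% each by
default) are appended *in addition to* the configured stratum sizes, and
within-stratum missingness defaults to zero. This gives the exclusion
filters real work while keeping the post-filter strata exactly at their
configured sizes, so descriptive replication can be asserted exactly.
Missingness rates implied by the published accounting (including 11.4%
missing prenatal care) are available via `paper_missingness_rates()` and
are injected completely at random — the source reports no missingness
mechanism, so MCAR is the only defensible default.

What the generator does **not** emulate: secular trends across calendar
years, seasonality, within-mother correlation between births, gestational
age in weeks (only the dichotomous PTB flag), correlation between education
and covariates within a stratum, and any real-data relationship between
missingness and risk. Passing recovery tests therefore show that the
pipeline estimates what it claims to estimate under a known mechanism —
not that the substantive findings would replicate on real registry data.

## Cohort construction

Exclusions run in a fixed, documented order: non-singleton → under 20 →
non-Hispanic → missing birthweight → missing nativity → missing ethnic
ancestry → missing education → (fully-adjusted mode) missing any covariate.
The source reports counts but not an order, and overlap attribution depends
on order — a record missing both nativity and education counts against
nativity here. The ledger is conservative by construction (input = output +
sum of removals; property-tested on random registries) and idempotent.
`published_cohort_ledger()` encodes the published accounting itself; the
published field-level missingness counts sum to more than the cumulative
exclusion (records can miss several fields), so they are carried as an
attribute rather than as stacked ledger rows.

Recoding caps education at 17 completed years, maps age to the five
categories (20–24 reference), parity to 0/1–4/5+ (1–4 reference), keeps the
three Kessner levels (adequate reference), and sets the medical-risk
dichotomy when any of the eight recorded conditions is present.

## Problem sizes in the checks

The recovery study in the acceptance suite scales the preset to ~50,000
births and fits the age-adjusted model with the default desk-scale MCMC,
checking that posterior mean reference risks fall within 3 posterior SDs of
the generating truth on at least 95% of the (stratum × education) grid, and
that the generator's qualitative structure — flatter foreign-born
gradients, nativity contrasts shrinking toward zero at high education — is
visible in the fitted surfaces. Interval calibration is checked across 40
independent registry replicates at a smaller scale. The fully-adjusted
model, whose collapsed-cell count (and hence cost) grows with the number of
distinct covariate patterns, is exercised end-to-end at a few thousand
records in the pipeline tests.

## Known limitations

* The fully-adjusted sampler's per-iteration cost scales with the number of
  unique covariate patterns; at hundreds of thousands of records it is
  markedly slower than the age-adjusted fit (which is bounded at 1,260
  cells). Batching patterns or thinning covariates would help if
  production-scale fully-adjusted runs were needed.
* Risk differences are reported for the education grid only; no attempt is
  made to standardise over an education distribution.
* The generator draws covariates independently of education within a
  stratum; real registries confound the two, so covariate-adjustment
  comparisons on synthetic data are cleaner than they would be in practice.
* Model comparison (e.g. against a non-hierarchical or linear-in-education
  fit) is out of scope; the package estimates one model family well rather
  than adjudicating between families.
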