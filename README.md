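# ptbhier

Bayesian hierarchical modelling of preterm-birth (PTB) risk by completed
years of maternal education, maternal nativity (US-born vs foreign-born),
and Hispanic subgroup.

## What it does, and for whom

Reproductive and social epidemiologists studying the "Hispanic Paradox"
need absolute PTB risks — not odds ratios — across fine categorisations of
education (integer years 0–17) for 7 Hispanic subgroups × 2 nativity
classes. Saturated estimates are too noisy in small strata; a pooled curve
erases the heterogeneity of interest. `ptbhier` fits the middle ground: a
Bayesian random-effects logistic regression in which each stratum has its
own education dose-response, modelled with restricted quadratic splines,
and stratum curves borrow strength across ethnic groups within a nativity
class.

For birth *i* in ethnic group *j* and nativity class *k*:

    Y_ijk ~ Bernoulli(p_ijk)
    logit p_ijk = delta_jk + sum_g alpha_gjk q_g(edu) + sum_m beta_m x_m

    delta_jk  ~ N(mu_0k, 1/tau_0)        alpha_gjk ~ N(mu_gk, 1/tau_g)
    mu_gk     ~ N(0, 1)                  tau_g     ~ Gamma(0.1, 0.1)
    beta_m    ~ N(0, 10)

with spline terms q1(e) = e, q2(e) = (e−8)₊² − (e−13)₊²,
q3(e) = (e−11)₊² − (e−13)₊² (knots 8, 11, 13 years; linear outside the knot
span, C¹ everywhere). The posterior is sampled by a fully conjugate
Pólya-Gamma Gibbs sampler (compiled Devroye sampler, seed-reproducible),
and summarised as absolute-risk surfaces and native-minus-foreign risk
differences with 95% posterior intervals, computed draw-wise.

Because the study's registry microdata cannot be redistributed, the package
includes a synthetic vital-statistics generator whose preset reproduces the
published descriptive structure (stratum sizes, education moments, PTB
marginals, covariate prevalences) with a *known* ground-truth dose-response,
so the whole pipeline is testable end-to-end: simulate → filter → recode →
fit → summarise → export.

## Worked example

```r
library(ptbhier)

params   <- make_table1_preset(scale = 0.1)          # ~26,000 births
registry <- generate_registry(params, seed = 2026)
filtered <- apply_exclusions(registry, mode = "age")
filtered$ledger
#> Exclusion ledger (age-adjusted cohort)
#>   input records: 27516
#>                 rule removed remaining
#>        non_singleton     519     26997
#>             under_20     519     26478
#>         non_hispanic     519     25959
#>  missing_birthweight       0     25959
#>     missing_nativity       0     25959
#>    missing_ethnicity       0     25959
#>    missing_education       0     25959
#>   retained: 25959 (94.3%)
```

The contamination records (twins, under-20, non-Hispanic) the generator
appended are removed rule by rule; the ledger always conserves records.
Fit the age-adjusted hierarchical model and check convergence:

```r
frame <- recode_cohort(filtered$cohort)
draws <- sample_posterior(frame,
                          spec   = model_spec(adjustment = "age"),
                          config = mcmc_config(chains = 4, iterations = 6000,
                                               burnin = 1000, thin = 5,
                                               seed = 1))
diagnostics(draws, c("alpha1[Mexicn,US]", "delta[Mexicn,US]", "tau0"))
#>           parameter    mean     sd rhat  ess
#> 1 alpha1[Mexicn,US]  0.0466  0.273    1 1968
#> 2  delta[Mexicn,US] -2.6813  0.244    1 3348
#> 3              tau0 19.5437 10.335    1 3760
```

Split R-hat at 1 and four-digit effective sample sizes from 4,000 retained
draws: the conjugate Gibbs sampler mixes essentially as well as independent
sampling here. Posterior absolute risks at the reference covariate pattern
(age 20–24 in this age-adjusted fit):

```r
surface <- risk_surface(draws)
subset(surface, ethnicity == "Puerto Rican" & education %in% c(8, 12, 17))
#>       ethnicity     nativity education   mean median lower95 upper95
#> 45 Puerto Rican      US-born         8 0.0893 0.0887  0.0663  0.1154
#> 49 Puerto Rican      US-born        12 0.0927 0.0925  0.0800  0.1069
#> 54 Puerto Rican      US-born        17 0.0418 0.0412  0.0280  0.0593
#> 63 Puerto Rican Foreign-born         8 0.0817 0.0808  0.0545  0.1133
#> 67 Puerto Rican Foreign-born        12 0.0859 0.0850  0.0668  0.1083
#> 72 Puerto Rican Foreign-born        17 0.0551 0.0534  0.0282  0.0921
```

Roughly 9% PTB risk through secondary education falling to ~4–6% at 17
years, and — as the generator is configured, mirroring the published
finding — island-born Puerto Ricans decline like the mainland-born, with no
nativity advantage. The nativity contrast itself, formed within each
posterior draw:

```r
rd <- risk_difference_surface(surface)
subset(rd, ethnicity == "Mexican" & education %in% c(8, 17))
#>    ethnicity education   mean median lower95 upper95
#> 1    Mexican         8  0.025  0.015  -0.040   0.141
#> 10   Mexican        17 -0.027 -0.028  -0.078   0.042
```

A ~2.5-point US-born excess risk at 8 years of education that vanishes (and
flips sign) by 17 years: the protective effect of foreign birth fades with
education. `export_figures()` writes the composite four-panel risk figure,
the risk-difference panels, and per-group interval plots;
`run_pipeline(run_config(...))` drives all stages with a manifest, and
`inst/scripts/ptbhier-pipeline.R` exposes them as shell subcommands
(`simulate | filter | fit | report | run`).

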