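# adlirt

Bayesian longitudinal item response modelling of disability in activities
of daily living (ADL), for researchers in aging and end-of-life
epidemiology.

The six-item Katz scale scores bathing, dressing, toileting, transferring,
continence and feeding on a three-point ordinal scale (0 no limitation,
1 partial limitation, 2 totally limited). Summed scores hide *where* on
the disability continuum each ability is lost. `adlirt` instead fits a
Samejima graded response model with a longitudinal latent trait,

    P(Y[s,t,i] >= k | theta[s,t]) = plogis(alpha_i * theta[s,t] - kappa[i,k])
    theta[s,t] = gamma0_s + gamma1_s * t
    gamma1_s  = gamma1'_s + Z_s beta,   gamma1'_s ~ N(mu, sigma1^2)

where `alpha_i` is the item's discrimination, `kappa[i,partial] <
kappa[i,total]` are its ordered difficulty thresholds, `theta` is latent
disability (larger = worse), `t` is years in follow-up, and `Z_s` holds
sex, standardized baseline age, residence, standardized education and
marital status. Sorting the twelve thresholds by `kappa` yields the
hierarchical order in which abilities are lost; `mu` is the population
mean annual increase in disability. Estimation is by
Metropolis-within-Gibbs MCMC with the latent scale anchored by a fixed
N(0,1) prior on the subject intercepts. A second stage rescales the
latent scores to [-3, 3], aligns them to years before death, and fits a
random-intercept/random-slope mixed model with covariates and cross-group
mean trajectories.

Because the motivating cohort data are agreement-gated, the package ships
a mortality-truncated synthetic-panel generator whose defaults reproduce
the cohort's published marginals (60.2% female, 63.1% rural, 80.8%
without spouse, age 91.3 (SD 9.6), median follow-up ~3 years truncated at
death) and whose generating truth defaults to the published item
estimates (`katz_reference_params()`). Every estimator in the package is
validated by parameter recovery against that truth.

## Worked example

```r
library(adlirt)

## the ADL-loss hierarchy implied by the reference item estimates
ranked <- rank_thresholds(threshold_entries(katz_reference_params()))
head(ranked, 3)
#>        item   level  kappa rank
#> 1   bathing partial -1.396    1
#> 2 toileting partial -0.904    2
#> 3   bathing   total -0.374    3
threshold_gap(threshold_entries(katz_reference_params()), "bathing")
#> [1] 1.022

## simulate a cohort from known truth and recover it
cfg <- generator_config(n_subjects = 200, fixed_visits = c(0, 1, 2, 3),
                        seed = 42)
gen <- generate_dataset(cfg)
gen$panel
#> katz_panel: 200 subjects, 4800 response records (4560 observed)

fit <- run_mcmc(gen$panel, mcmc_config(n_burnin = 1000, n_keep = 1000,
                                       n_chains = 2, seed = 42))
s <- summarize_posterior(fit)
subset(s, parameter %in% c("kappa_partial[bathing]", "alpha[toileting]",
                           "kappa_total[continence]", "mu", "slope_sd"))[, 1:5]
#>                parameter   mean     se   q2.5  q97.5
#>   kappa_partial[bathing] -1.393 0.1487 -1.682 -1.110
#>         alpha[toileting]  4.481 0.4954  3.567  5.431
#>  kappa_total[continence]  3.649 0.2272  3.227  4.125
#>                       mu  0.801 0.1357  0.547  1.092
#>                 slope_sd  0.468 0.0441  0.387  0.558
```

The generating truth was `kappa_partial[bathing] = -1.396`,
`alpha[toileting] = 4.124`, `kappa_total[continence] = 3.647`,
`mu = 0.857`, `slope_sd = 0.5`: at 200 subjects every 95% credible
interval above covers its truth (as do all twelve threshold intervals),
and the recovered threshold ranking agrees with the generating hierarchy
at Spearman rank correlation 0.97 — off only by a swap among near-tied
thresholds. The first and last thresholds bracket the continuum from
partial bathing (lost first) to total continence (lost last).

```r
## disability trajectories against years before death
visits <- extract_scored_visits(fit, gen$panel, seed = 42)
mm <- fit_mixed_model(visits)
subset(mm$fixed_effects,
       term %in% c("(Intercept)", "years_before_death", "sex"))
#>                term estimate     se
#>         (Intercept)    0.718 0.1199
#>  years_before_death   -0.137 0.0224
#>                 sex    0.127 0.1088
```

On the rescaled [-3, 3] axis, disability is 0.137 units lower per year
*further from* death — i.e. it worsens as death approaches. An
end-to-end run (simulate, fit, hierarchy tables, trajectory curves, JSON
report) is available as `run_pipeline(pipeline_config(out_dir = "..."))`.

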