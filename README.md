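# traitgrowth

Hierarchical Bayesian trait-based growth models for multi-species fire
chronosequences, and a quantitative test of whether such models *transfer*:
can a model trained on one ecosystem predict the growth trajectories of
species in another, from their functional traits alone?

The package is for ecologists and biostatisticians working with
space-for-time height data — many species, one `(age, height)` observation
per plant across sites of different time since fire — who want to (i) fit
species growth curves jointly with partial pooling, (ii) ask which traits
drive which aspects of growth, and (iii) score out-of-sample predictions for
species the model has never seen.

## The model

Observed heights are lognormal around a sigmoidal (Hillslope) growth curve:

$$H_i \sim \mathrm{lognormal}(\log \mu_{i,j},\ \sigma^2), \qquad
\mu_{i,j} = \frac{\alpha_j}{1 + \exp[-b_j (T_i - c_j)]},$$

where, for species $j$: $\alpha_j$ is asymptotic height (cm), $b_j$ the
maximum relative growth rate (cm cm⁻¹ yr⁻¹), and $c_j$ the age (years) of
maximum growth. Each log growth parameter is a linear function of
standardized functional traits plus a species random effect, e.g.

$$\alpha_j = \exp(\beta_0 + \beta_1 z_{\mathrm{SLA},j} + \varepsilon_j),
\qquad \varepsilon_j \sim \mathrm{Normal}(0, \tau^2),$$

with vague Normal priors (precision 10⁻⁴) on coefficients and
half-Cauchy(25) priors on all standard deviations. Fitting is by an adaptive
Metropolis-within-Gibbs sampler with exact conjugate updates for the
sub-model coefficients; convergence is monitored with the
Brooks–Gelman–Rubin statistic. Model checking includes DIC,
observed-vs-predicted R², multilevel (Gelman) R² and pooling factors per
sub-model, backward selection over trait→parameter maps, and
credible-interval overlap screening. Out-of-sample prediction integrates
over the fitted random-effect distribution (Monte Carlo imputation of the
unseen species' heights) and is scored with RMSD and mean deviance against
target-data reference fits.

A synthetic-data module generates multi-ecosystem chronosequence datasets
with known ground truth, so every stage is verifiable by parameter recovery
without any field data.

## Worked example

Simulate a 15-species, 600-plant chronosequence whose true trait effects are
−0.3 (SLA → height), +0.3 (leaf N → growth rate), +0.3 (seed mass → timing),
then refit:

```r
library(traitgrowth)

cfg <- preset_recovery_config()
sim <- generate_multi_ecosystem(cfg, seed = 42)
sim$data
#> <growth_data> 600 height observations, 15 species, 1 ecosystem(s): train

fit <- sample_posterior(
  sim$data,
  structure = trait_structure(alpha = "sla", b = "leaf_n", c = "seed_mass"),
  config = mcmc_config(chains = 3, iterations = 6000, burnin = 3000,
                       thin = 5, seed = 42)
)
glance(fit)
#>   n_species n_chains n_retained n_slopes max_rhat converged ensemble
#> 1        15        3        600        3     1.04 TRUE      FALSE

td <- tidy(fit)
td[td$term %in% c("beta_alpha_sla", "beta_b_leaf_n", "beta_c_seed_mass", "sigma"), ]
#>   term             estimate std.error median conf.low conf.high  rhat
#> 1 beta_alpha_sla     -0.318   0.0506  -0.319   -0.413    -0.217 1.00
#> 2 beta_b_leaf_n       0.272   0.0446   0.272    0.183     0.358 1.00
#> 3 beta_c_seed_mass    0.293   0.0728   0.294    0.153     0.439 0.999
#> 4 sigma               0.206   0.00606  0.206    0.194     0.219 1.000

obs_pred_r2(fit, sim$data)
#> [1] 0.861
c(gelman_r2 = gelman_r2_submodel(fit, "alpha"), pooling = pooling_factor(fit, "alpha"))
#> gelman_r2   pooling
#>     0.787     0.140
```

All three trait slopes are recovered with 95% intervals covering the truth,
the observation sd (true 0.2) is estimated at 0.206, and the SLA sub-model
explains ~79% of the between-species variance in log asymptotic height.
`autoplot(fit)` draws the coefficient forest plot; `plot_trajectories(fit,
sim$data)` overlays posterior-median curves on the data. For transfer,
`predict_new_species()` predicts trajectories for unseen species from traits
alone and `transfer_report()` scores them (RMSD, signed mean deviance)
against reference fits to the target data, alongside a no-trait baseline.

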