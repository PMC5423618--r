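---
title: "Hierarchical trait-based growth models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical trait-based growth models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitgrowth)
```

## The model

`traitgrowth` fits height growth of many co-occurring woody species jointly,
using a space-for-time (chronosequence) design: sites differing in time since
fire stand in for a time series, and every plant contributes one
`(age, height)` observation.

**Observation model.** A measured height $H_i$ (cm) of individual $i$,
belonging to species $j$, is lognormal around the growth curve:

$$\log H_i \sim \mathrm{Normal}(\log \mu_{i,j},\; \sigma^2).$$

The log-scale location is $\log \mu_{i,j}$, so $\mu_{i,j}$ is the **median**
height at that age; this is the standard convention for a lognormal
parameterised by a location and a precision, and the only reading under which
the process model below composes cleanly. Estimates of $\sigma$ would shift
slightly under a mean parameterisation; conversions are elementary and the
choice is documented here once rather than scattered through the code.

**Process model.** Heights follow the Hillslope curve, a three-parameter
re-parameterisation of the logistic:

$$\mu_{i,j} = \frac{\alpha_j}{1 + \exp[-b_j (T_i - c_j)]},$$

with biologically interpretable species-level constants: $\alpha_j$ the
asymptotic height (cm), $b_j$ the maximum relative growth rate
(cm cm$^{-1}$ yr$^{-1}$), and $c_j$ the age (years) at which absolute growth
peaks. `hillslope_height()`, `absolute_growth_rate()` and
`relative_growth_rate()` expose the curve and its derived rates; the identity
$\mathrm{AGR} = \mathrm{RGR} \times \mu$ and the maximum $\alpha b / 4$ at
$T = c$ are tested exactly.

**Trait sub-models.** Each log growth parameter is a linear function of
standardized functional traits plus a species random effect, e.g.

$$\alpha_j = \exp(\beta_0 + \beta_1 \, z_{\mathrm{SLA},j} + \varepsilon_j),
\qquad \varepsilon_j \sim \mathrm{Normal}(0, \tau_\alpha^2),$$

and likewise for $b_j$ (leaf nitrogen) and $c_j$ (seed mass) in the default
structure; `trait_structure()` lets any of the four traits (SLA, wood
density, seed mass, leaf nitrogen) predict any of the three parameters. The
exponential link guarantees positivity. An empty structure is the no-trait
baseline: a grand mean plus species random effects per parameter.

**Priors.** Sub-model coefficients get vague Normal(0, sd = 100) priors —
i.e. precision $10^{-4}$; a literal sd of $10^{-4}$ would pin every
coefficient at zero, so the precision reading is the default and the sd is
configurable via `mcmc_config(prior_beta_sd=)`. All standard deviations
(observation, random effects, ensemble site offsets) get half-Cauchy(0, 25)
priors, weakly informative on the scales involved.

**Ensemble model.** `fit_ensemble()` fits several ecosystems jointly, with
each growth parameter's intercept varying by ecosystem:
$\beta_0 \to \beta_0 + \delta_s$, $\delta_s \sim \mathrm{Normal}(0,
\mathrm{sd_{site}})$, with a half-Cauchy(25) prior on each per-parameter
$\mathrm{sd_{site}}$. (One offset sd per growth parameter, since the three
sub-models are independent.)

## Sampling

`sample_posterior()` runs an adaptive random-walk Metropolis-within-Gibbs
sampler written for this model's structure:

- **Species blocks.** Given the hyperparameters, species are conditionally
  independent, so each sweep proposes new log parameters for *all* species at
  once (one vectorised Metropolis step per growth parameter) and
  accepts/rejects species-wise.
- **Coefficients.** Given the species-level log parameters and $\tau$, the
  sub-model coefficients have an exact conjugate multivariate-normal
  conditional; they are Gibbs-sampled, which removes the slowest mixing
  direction entirely.
- **Standard deviations.** Log-scale random-walk steps with the half-Cauchy
  prior and Jacobian.

Proposal scales adapt in batches of 50 during burn-in (target acceptance
0.44) and freeze afterwards, so the post-burn-in chain is a valid fixed
kernel. Chains start from over-dispersed jitter (multiplicative lognormal,
sd 0.2) around `init_from_single_species()`, a deterministic per-species
least-squares fit of the curve to log heights with a heuristic fallback
($\alpha = 1.1 \times$ max height, $c$ = median age,
$b = 4 \cdot \mathrm{max height} / (\alpha \cdot \mathrm{age\ range})$) for
species with too few distinct ages. Defaults are 3 chains of 20,000
iterations, half burn-in, thinning 10; the run is reproducible from
`mcmc_config(seed=)` alone.

Convergence is monitored with the Brooks–Gelman–Rubin statistic
$\hat R = \sqrt{((n-1)/n \cdot W + B/n)/W}$ per quantity (`rhat()`); a fit
with any $\hat R > 1.1$ is returned with a prominent warning and
`converged = FALSE`, never silently. The sampler's correctness is tested
against the analytic posterior of a conjugate reduction (all parameters but
the log-asymptote pinned via the `fixed` argument), by moment comparison and
a Kolmogorov–Smirnov test.

## Model checking and comparison

- `dic()`: Spiegelhalter's DIC, $\bar D + p_D$ with
  $p_D = \bar D - D(\bar\theta)$. The plug-in $\bar\theta$ is the posterior
  mean **on the log scale** of the species parameters and of $\sigma$
  (medians of the natural-scale draws are available through `tidy()`).
- `obs_pred_r2()`: squared Pearson correlation between observed heights and
  posterior-median expected heights per individual — the overall fit
  statistic.
- `gelman_r2_submodel()` and `pooling_factor()`: the multilevel
  variance-explained statistic
  $1 - \mathbb{E}_d[V_j(\varepsilon_j)]/\mathbb{E}_d[V_j(\log \theta_j)]$
  and the pooling factor
  $1 - V_j(\mathbb{E}_d[\varepsilon_j])/\mathbb{E}_d[V_j(\varepsilon_j)]$,
  in their standard published forms (no finite-sample corrections; the
  variances are ordinary sample variances across species, averaged over
  draws).
- `ci_overlap_test()`: the approximate screening rule for two 95% intervals
  — just touching (or disjoint) rejects at $p<0.01$, overlap shorter than
  half the mean interval length rejects at $p<0.05$. "Half their length" is
  ambiguous for unequal intervals; we use half of the **mean** of the two
  lengths.

### Selecting a trait structure

`backward_selection()` starts from the full candidate map (every trait on
every parameter), repeatedly refits with each remaining slope removed, drops
the cheapest slope, and stops when any further drop would cost more than
`tolerance` (default 0.005 — deliberately less knife-edge than the R²
differences that typically separate nested structures).

**Which R² to score with is a real design decision.** The obvious choice —
`obs_pred_r2()` on the full posterior predictions — turns out to be
*insensitive and anti-parsimonious* for this purpose, and we verified this
across simulation regimes: because the species random effects absorb
whatever the traits do not explain, and because weakly pooled species
estimates partially track the per-species observation noise present in the
very data being scored, the in-sample R² of the **no-trait** model is
consistently the highest, and removing an informative slope does not lower
it. A selection rule based on it therefore cannot recover a known generating
structure. The default score is instead `trait_level_r2()`: predictions from
the trait sub-models alone (species effects set to zero), correlated with
observations on the log scale — the model's residual scale, which weighs a
short, fast-growing shrub as much as a tall tree. This statistic collapses
when an informative slope is removed and moves little when a spurious slope
is added. The literal full-prediction scoring remains available via
`score = "full"`.

Even with the sharper score, exact recovery of a generating structure by
greedy threshold selection over twelve candidate slopes is fragile at small
sample sizes: correlated trait draws let one trait stand in for another
(e.g. seed mass replacing SLA on the height sub-model), and refit-to-refit
Monte Carlo noise competes with the tolerance. Our selection experiments
(`selection_recovery_experiment()`, `preset_selection_config()`) document
this honestly rather than hiding it; treat selection output as a hypothesis
about structure, as one should in any case with greedy model search.

## Out-of-sample transfer

`predict_new_species()` predicts growth trajectories for species the model
has never seen, from traits alone: for each posterior draw, the new species'
traits are standardized with the **training** statistics (never their own —
`trait_stats()` carries provenance for exactly this reason), a fresh random
effect is drawn from the fitted $\mathrm{Normal}(0, \tau)$ per parameter,
the three growth parameters are formed through the sub-models, and the curve
is evaluated. This integrates over everything the model does not know about
the new species, and is equivalent to imputing the species' missing heights
by Monte Carlo within the model. Setting `epsilon = "zero"` gives the
trait-line point prediction instead. Extrapolation beyond the training trait
range is permitted and never clipped (it is reported); transfer failure under
non-overlapping trait distributions is a finding, not an error.

`transfer_report()` scores predictions per species with RMSD
($\sqrt{\mathrm{mean}((\mathrm{pred}-\mathrm{ref})^2)}$, accuracy) and mean
deviance (signed bias; positive = over-prediction), against reference
trajectories that are by default the posterior-median curves of a no-trait
hierarchical model fitted to the *target* data — predictions are compared to
what the target data themselves say each species does, not to raw noisy
points (a `reference = "observed"` mode exists). The evaluation grid is 50
evenly spaced ages spanning the target chronosequence. The same report
scores the no-trait training model, the baseline any useful trait model must
beat. The identity $\mathrm{RMSD}^2 = \mathrm{MD}^2 +
\mathrm{Var}(\mathrm{deviance})$ holds exactly and is tested.

## The synthetic-data generator

`simulation_config()` / `generate_multi_ecosystem()` produce multi-ecosystem
chronosequence datasets with exactly the statistical structure the model
assumes, with full ground truth recorded: traits are drawn from
ecosystem-specific multivariate normals on log scales (positive,
right-skewed, optionally shifted so ranges barely overlap between
ecosystems); species parameters follow the log-linear sub-models with known
coefficients; ages come from a discrete set of site ages (default 8 sites
spanning the range, individuals spread evenly across sites in random order —
a chronosequence, not a continuous sample; a continuous mode exists); and
heights are lognormal around the curve. `preset_three_ecosystems()` mimics
the qualitative contrast seen across south-eastern Australian fire
chronosequences — a fast-growing, short, early-peaking semi-arid system, an
intermediate mixed system, and a slow, tall, late-peaking wet-forest system
(grand means of log growth rate near +1.35, +0.15 and −1.13) — as preset
constants for realistic-looking simulations, not as quantities to be
recovered.

What the generator does **not** emulate: resprouting species, age
measurement error, within-species trait variation, spatial structure among
sites, and trait–trait causal structure beyond a correlation matrix. Passing
tests on synthetic data therefore demonstrate the machinery is correct under
the model's own assumptions, not that the model is adequate for any
particular field system.

## Experiment configurations and problem sizes

The validation experiments are sized for a desk-scale single-CPU run while
keeping each check statistically meaningful:

- **Parameter recovery** (`preset_recovery_config()`): 10 replicates of 15
  species × 40 individuals, slopes (−0.3, +0.3, +0.3), σ = 0.2, random-effect
  sds 0.2/0.15/0.2 (moderate species scatter, typical of these fits), chains
  3 × 4,000 (half burn-in, thin 4). Checked: 95% intervals cover each true
  slope in ≥ 8/10 replicates, absolute mean bias < 0.1.
- **Structure selection** (`preset_selection_config()`): 10 replicates of 14
  species × 5 individuals on a 0–12-year chronosequence, slopes (−0.8, +1.0,
  +0.8), random-effect sds 0.05, σ = 0.15, tolerance 0.03, chains 2 × 1,000.
  The regime was designed by power analysis: few noisy observations per
  species so pooling matters, ages confined to the rising phase so the
  growth-rate and timing sub-models leave an imprint on heights.
- **Transfer**: paired train/target ecosystems of 10 species × 10
  individuals; the over-prediction experiment shifts the target's grand-mean
  log asymptote by −1 (a uniformly shorter flora); the ensemble-correlation
  experiment opposes height and growth-rate levels (±0.8) between two
  ecosystems with no trait effects, so the α–b correlation exists only
  across systems.
- **Sampler calibration**: conjugate reduction with 3 chains × 2,000
  iterations, thinned to near-independence for the KS test.

## Numerical choices

- Logistic terms route through `plogis(..., log.p = TRUE)`; no overflow for
  exponents anywhere in ±700.
- Trait standardization on the raw scale by default; per-trait
  log-transform-before-standardizing is available (`log_traits`), common for
  seed mass, off by default since either convention is defensible.
- Degenerate inputs fail loudly: zero trait variance is an error at
  `trait_stats()`; species with fewer than two distinct ages are flagged at
  `growth_data()` and refuse to enter a fit; `rhat()` reports `NA` (chains
  constant and equal) or `Inf` (constant but different) with warnings rather
  than guessing.
- Candidate refits in `backward_selection()` reuse one seed so comparisons
  are paired; candidates are evaluated in sorted order, making the whole
  procedure invariant to species and row ordering.
- In `tidy()`, intervals are central posterior quantiles; the point estimate
  is the mean, with the median alongside.

## Known limitations

- The sampler is a general-purpose random-walk scheme; for very weakly
  identified species (few observations all on the curve's plateau) mixing of
  $c_j$ can be slow, which the $\hat R$ table will show. Run longer chains
  rather than trusting a flagged fit.
- DIC is reported because it is the conventional comparison statistic for
  this model family; it shares the known weaknesses of plug-in deviance
  measures and is not a substitute for the recovery experiments.
- Greedy backward selection explores one path through structure space; with
  correlated traits the chosen structure is not unique, and bootstrap or
  exhaustive comparison would be needed for strong claims.
- Transfer scores are only as good as the target-side reference fits; for
  target species with very few observations, the "reference" trajectory is
  itself uncertain, and `reference = "observed"` may be fairer.
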