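---
title: "A Bayesian multiple-changepoint model for state-level overdose death rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian multiple-changepoint model for state-level overdose death rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opioidwaves)
```

## The problem

The US opioid epidemic is commonly described as three waves — a rise in
deaths involving prescription opioids from the late 1990s, a rise in
heroin-involved deaths from around 2010, and a rise in synthetic-opioid
(fentanyl) deaths from the mid-2010s — but states differ substantially in
when each wave arrived and how severe it was. Characterising that
heterogeneity requires estimating, for every state and drug category, a
death-rate time series of unknown shape, with abrupt shifts, from counts
that are small in many states. `opioidwaves` implements a single
hierarchical model that does this jointly for all states and drug
categories, together with the ICD-10 coding rules that produce the input
counts and a synthetic-data generator that stands in for restricted
line-level mortality files.

## From death certificates to counts

A death enters the analysis when its underlying cause is drug poisoning:
ICD-10 codes X40–X44 (unintentional), X60–X64 (intentional
self-poisoning), X85 (assault), or Y10–Y14 (undetermined intent). Drug
involvement is read from the multiple-cause T-codes: T40.2/T40.3 flag
*prescription* opioids, T40.1 *heroin*, T40.4 *synthetic* opioids. A
fourth, mutually exclusive *unspecified* category captures deaths coded
only with T50.9, or T40.6 without any of T40.1–T40.4; it exists to surface
reporting differences across states and years. A death involving several
named drugs counts once in each named category, so category totals
deliberately exceed the number of distinct deaths. Codes are canonicalized
by uppercasing and stripping dots, and extended subcodes match their
4-character stem by prefix — multiple-cause files vary in both respects,
and the published coding rules are stated at stem granularity.

Counts are aggregated to a complete state × year × drug lattice with
per-state-year populations (the `counts_table` container), and each state
carries one of the ten CMS (Centers for Medicare and Medicaid Services)
regions. The shipped region map covers the 48 contiguous states plus DC;
it follows the public CMS regional-office definitions and can be replaced
via `read_region_map()`.

## The model

Counts are Poisson with an exposure equal to population over 100,000, so
rates are directly interpretable per 100k residents:

$$y_{std} \sim \text{Poisson}(E_{st}\,\theta_{sd,k(t)}), \qquad
E_{st} = P_{st}/10^5 .$$

Each state–drug series is piecewise constant: binary indicators
$z_{std} \in \{0,1\}$ at transition years $t = 2,\dots,T$ mark the start of
a new *regime*, and each regime carries its own rate
$\theta \sim \text{Gamma}(a_d, b_d)$. The Gamma prior is conjugate to the
Poisson likelihood, so a segment's rate can be integrated out in closed
form:

$$\log \int \prod_t \text{Pois}(y_t \mid E_t\theta)\,
\text{Ga}(\theta \mid a,b)\,d\theta
= \textstyle\sum_t [y_t\log E_t - \log y_t!] + a\log b - \log\Gamma(a)
+ \log\Gamma(a+Y) - (a+Y)\log(b+\sum E_t).$$

The changepoint process is a *centered autologistic* chain. With
linear predictor $\beta_{0d} + \phi_{r(s),d}$ and independence mean
$\mu_{sd} = \text{logit}^{-1}(\beta_{0d} + \phi_{r(s),d})$,

$$P(z_{std}=1 \mid z_{s,t-1,d}) =
\text{logit}^{-1}\!\big(\beta_{0d} + \phi_{r(s),d} +
\eta_d\,(z_{s,t-1,d} - \mu_{sd})\big),$$

with the first transition year using $\mu_{sd}$ itself. Centering the lag
term by $\mu$ keeps $\beta_{0d} + \phi_{r(s),d}$ interpretable as the
marginal log odds of a change, while $\eta_d > 0$ encodes volatility
clustering: a state that changed last year is more likely to change again.
The regional effect vectors $\phi_r = (\phi_{r1},\dots,\phi_{rD})$ are
multivariate normal across drugs, $\phi_r \sim \text{MVN}(0,\Sigma_\phi)$,
so that, e.g., a region prone to heroin regime changes can share that
propensity with synthetic opioids. Priors are proper but diffuse:
$\beta_{0d}, \eta_d \sim N(0, 10^2)$ and
$\Sigma_\phi \sim \text{IW}(D+2, I_D)$.

Several aspects of this parameterization were genuinely open design
choices:

* **Directed-in-time autologistic.** We realise the centered autologistic
  process as a lag-1 conditional chain (centering by the independence
  mean, after Caragea & Kaiser), which yields a tractable joint density.
  A symmetric Markov-random-field formulation would require an
  intractable temporal normalizer and adds nothing at lag 1.
* **Gamma rather than log-normal rates.** Gamma regime rates give closed-
  form collapsed indicator updates and conjugate rate redraws. A log-scale
  normal prior is a plausible alternative; it would force Metropolis
  updates for every rate and was rejected on that ground.
* **Where the regional effect lives.** $\phi$ enters the changepoint
  process, not the rate level: regions share *timing* propensity, while
  rate levels are already pooled through the common Gamma prior.
* **No year fixed effects.** Year-to-year variation in the log odds of
  change arises only through the autoregressive term; with 23 years and
  49 states, free year effects would be weakly identified against it.
* **Fixed rate-prior constants.** $a_d = 0.5$, $b_d = 0.05$ (prior mean
  10 per 100k, variance 200) are fixed by default rather than
  hyper-learned — diffuse on the scale of observed overdose rates
  (roughly 0.5–80 per 100k) and identifiable at desk scale. Both are
  configurable in `model_hyperparams()`.

## Inference

`run_mcmc()` is a Metropolis-within-Gibbs sampler with four blocks:

1. **Collapsed indicator sweep** (`update_indicators`, compiled): each
   $z_{std}$ is resampled from its full conditional with the adjacent
   segment rates integrated out. Flipping $z_{std}$ merges or splits the
   two neighbouring segments; the ratio needs only the collapsed segment
   scores and the Bernoulli masses of $z_{std}$ and its successor (whose
   conditional depends on $z_{std}$ through the centered lag term).
   Collapsing matters: non-collapsed single-site updates mix poorly when
   rates are well identified.
2. **Conjugate rate redraw** (`update_rates`):
   $\theta \sim \text{Gamma}(a+Y_{\text{seg}},\, b+E_{\text{seg}})$.
3. **Random-walk Metropolis** on $\beta_{0d}$ and $\eta_d$ against the
   autologistic density plus their normal priors.
4. **Regional effects**: joint Gaussian proposal per region vector, then a
   conjugate inverse-Wishart redraw of $\Sigma_\phi$ given all $\phi_r$.

Initialization sets $z = 0$, rates at empirical series means floored at
0.5 per 100k, hyperparameters at their prior centers. Proposal scales
adapt toward 30% acceptance during burn-in only, so detailed balance holds
for every retained draw. All randomness flows through R's RNG (including
the compiled sweep), making every stage bit-reproducible under a fixed
seed. All-zero series need no special casing: the Gamma prior keeps the
collapsed marginal finite.

The full analysis profile is 500,000 iterations, 250,000 burn-in, thinning
by 50 (5,000 retained draws). The test suite and examples run reduced
profiles — typically 20,000/10,000/10 on a 10-state × 23-year × 2-drug
lattice, which completes in well under a minute while leaving posterior
Monte-Carlo error far below the tolerances being checked. `mcmc_diagnostics()`
adds quantitative checks (split R-hat across chains, autocorrelation-based
ESS) on top of the usual visual trace inspection (`trace_plot()`).

## Posterior summaries

* `rate_summaries()` — cellwise posterior medians and equal-tailed 90%
  intervals of the per-year rate $\lambda_{std}$.
* `relative_risk()` — per draw $RR = \lambda_{st d}/\lambda_{s,t-1,d}$;
  a cell is flagged an increase (decrease) when
  $P(RR > 1) \ge 0.9$ ($P(RR < 1) \ge 0.9$). Within-regime years give
  $RR \equiv 1$, so flags respond to regime changes, not sampling noise.
* `changepoint_logodds()` — the posterior median autologistic linear
  predictor per state and, averaged on the log-odds scale before
  summarization, per region. The realized lag term is included by
  default; `lag_term = FALSE` reduces it to the independence value
  $\beta_0 + \phi$ (both conventions are defensible readings of an
  "average log odds of change"; the switch makes the choice explicit).
* `wave_onset()` — the earliest transition year where the posterior
  probability of an *upward* regime change
  ($z = 1$ and $\lambda_t > \lambda_{t-1}$) reaches 0.5. "Wave onset" has
  no standard operational definition; this conjunction rule reads
  "the wave started" as a posterior probability statement about a rise,
  and the threshold is a parameter.

## The synthetic-data generator

Access to line-level mortality files is restricted, so
`simulate_truth()` / `simulate_counts()` / `simulate_records()` generate
data with the structure the model assumes, at the study's aggregate scale:
49 (or fewer) jurisdictions × 23 years × 4 drug categories, populations
log-uniform on $[5\times10^5, 2\times10^7]$ held constant over years, and
piecewise-constant rates per 100k with baselines of 2–8 (prescription),
0.5–3 (heroin), 0.2–1 (synthetic) and 0.5–5 (unspecified). Each series
receives one upward onset changepoint drawn uniformly in its drug's
window — prescription 1999–2005, heroin 2010–2014, synthetic 2014–2021,
matching the recognised three-wave timing — with a multiplicative
log-normal jump of median ×2.5, then further changes (up or down) with
probability 0.15 per subsequent year to exercise multiple-changepoint
recovery. `simulate_records()` inverts the coding rules exactly, emitting
line-level records (including multi-drug and unspecified-only records)
that re-aggregate bit-for-bit to their source table.

What the generator does **not** emulate: spatial adjacency beyond region
membership, demographic structure, population drift, secular reporting
drift within the unspecified category, and over-dispersion relative to
Poisson. Passing recovery tests on this generator therefore demonstrates
that the sampler targets its posterior correctly and that the model
recovers structure *of the kind it assumes*; it does not validate the
Poisson or piecewise-constant assumptions against real mortality data.

## Numerical choices and limitations

* Exposures use the per-100k convention throughout; rates below roughly
  0.01/100k are effectively prior-dominated.
* The collapsed segment score drops terms common to merge/split moves, so
  indicator sweeps are O(1) per site after per-series cumulative sums.
* Posterior quantiles are type-7 (R default); intervals are equal-tailed.
* Degenerate inputs: constant chains are flagged (not errors) in
  diagnostics; empty lattices and incomplete lattices are errors at
  construction.
* The recovery studies in the tests use planted jumps of ×2.5 with
  expected counts ≥ 30/year. Weaker jumps or sparser counts yield
  posterior changepoint probabilities between 0 and 1 — correct posterior
  behaviour, but not a regime this package's acceptance thresholds
  describe.
* Figures use an approximate-geography tile grid rather than true
  choropleths; per-year panels replace animation.

## A worked sketch

```{r example, eval = FALSE}
cfg <- sim_config(n_states = 10, n_regions = 2,
                  drugs = c("heroin", "synthetic"),
                  baseline_range = list(heroin = c(2, 8),
                                        synthetic = c(2, 8)),
                  onset_window = list(heroin = c(2010, 2014),
                                      synthetic = c(2014, 2021)),
                  population_range = c(2e6, 2e7))
truth <- simulate_truth(cfg, seed = 1)
counts <- simulate_counts(truth, seed = 2)
draws <- run_mcmc(counts, truth$region_map,
                  model_hyperparams(drugs = counts$drugs, n_regions = 2),
                  mcmc_config(n_iter = 20000, n_burn = 10000, thin = 10,
                              seed = 3))
rate_summaries(draws)          # median rates and 90% intervals
wave_onset(draws, "heroin")    # recovered onset years
```
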