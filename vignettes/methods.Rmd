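---
title: "Measuring within- and between-group inequality in under-5 mortality risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring within- and between-group inequality in under-5 mortality risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u5equity)
library(dplyr)
```

## The problem

Progress on under-5 mortality is usually monitored by disaggregating death
rates across a single stratifier — most often household wealth quintiles.
That comparison answers "do the poor die more often?" but says nothing
about variability *within* each quintile. Because a child's risk of dying
before age five depends on many factors at once (wealth, residence,
maternal age and education, the sex of the child, birth order, whether the
mother has already lost a child, and unmeasured local conditions), births
in the same wealth quintile can face very different risks, and many of the
highest-risk births live outside the poorest quintile. Policies that target
the poorest 20% of households then miss a large share of the deaths they
hope to prevent.

`u5equity` implements an analysis pipeline that makes this precise for
survey birth histories of the DHS type (one record per birth, with the
household's wealth-index score, cluster, and maternal covariates):

1. estimate a *per-birth* posterior distribution of mortality risk with a
   Bayesian hierarchical logistic regression over the standard monitoring
   covariates, their interactions, and a sampling-cluster random effect;
2. decompose the variability of those risks within and between groups with
   a per-draw ANOVA \(R^2\);
3. compare *risk-based* targeting (the top 20% of model-ranked risk)
   against *poverty-based* targeting (the 20% poorest), reporting the
   efficiency gain with full posterior uncertainty.

Access to real DHS microdata is restricted, so the package ships a
synthetic birth-history generator with a known ground-truth risk surface;
every stage of the pipeline is exercised and tested against that truth.

## The risk model

For birth \(i\) in one survey,

\[
  \mathrm{died}_i \sim \mathrm{Bernoulli}(p_i), \qquad
  \operatorname{logit} p_i \;=\; \alpha + x_i^\top \beta + u_{c(i)},
\]

where the design row \(x_i\) contains:

* **main effects** — the five continuous covariates (maternal age at
  birth, wealth rank, maternal education in years, birth year, birth
  order), standardised and expanded into piecewise-linear spline bases
  (hinge columns \(\max(0, x - k)\)), plus the three centred binary
  covariates (male sex, urban residence, prior sibling death). Any
  continuous piecewise-linear trend with breaks at the knots is exactly
  representable, which is flexible enough for the smooth monotone dose
  -response shapes seen in mortality data while remaining cheap and
  interpretable. Default knots sit at the 25/50/75% quantiles of each
  covariate;
* **interactions** — every product of 2, 3, and 4 distinct base covariates
  (continuous covariates enter interactions linearly, on their
  standardised scale). With eight base covariates this yields
  \(\binom{8}{2}+\binom{8}{3}+\binom{8}{4} = 154\) interaction columns.
  Splines and interactions are deliberately separate devices: crossing
  full spline bases in four-way products would inflate the design by two
  orders of magnitude for no clear gain.

All coefficients of interaction order \(k\) share a scale,
\(\beta_j \sim N(0, \sigma_k^2)\) with
\(\sigma_k \sim \mathrm{Half\text{-}Normal}(s_k)\), and the schedule
\(s = (1, 0.5, 0.25, 0.125)\) halves with each order, so higher-order
interactions are admitted only when the data insist. The schedule is
configurable but must be strictly decreasing. The cluster effects are
\(u_c \sim N(0, \sigma_{loc}^2)\), \(\sigma_{loc} \sim
\mathrm{Half\text{-}Normal}(1)\), capturing unmeasured local risk, and
\(\alpha \sim N(0, 5^2)\) is essentially flat on the probability scale.

### Wealth enters as a rank

Raw wealth-index scores have arbitrary, survey-specific scales. Each
household's score is therefore mapped to its within-survey empirical
distribution value with the midpoint-rank convention
\((\mathrm{rank} - 0.5)/n\) over unique households (average ranks for
ties). The result lives strictly inside \((0,1)\), is invariant to any
monotone rescaling of the raw score, and is interpretable as relative
wealth. Quintiles are cut at 0.2, 0.4, 0.6, 0.8 (a survey-assigned
quintile column, when present, takes precedence). The exact tie and
ranking conventions are a documented package choice; any construction
that preserves ranks gives the same quintiles up to ties.

### The prior-death indicator is forward-looking

A birth is flagged only when an *earlier-order* sibling died *before* the
index birth date, so the covariate never leaks information from the
future; first births are always 0. A died sibling with no recorded death
date is counted only under the conservative bound "birth date + 5 years
precedes the index birth". The indicator is computed on the full recorded
birth history *before* the analysis-window filter, because an out-of-window
sibling death still informs the mother's risk.

### Analysis window

Births are kept when they occurred at least 5 but less than 10 years
before the survey: the half-open window \([5, 10)\) makes the two
exclusion rules partition time exactly. Younger births have censored
under-5 outcomes; older births suffer recall error.

## Sampling

The posterior is sampled by a Gibbs sampler with Polya-Gamma data
augmentation: given \(\omega_i \sim \mathrm{PG}(1, \eta_i)\), the
conditionals of \(\beta\) and \(u\) are exactly Gaussian, and the group
scales \(\sigma_k, \sigma_{loc}\) are updated by univariate slice sampling
on \(\log\sigma\). A centered scale update alone mixes poorly when a
block is strongly shrunk (the usual funnel: a small \(\sigma_k\) traps
its coefficients near zero, which in turn keeps \(\sigma_k\) small), so
each iteration interweaves a second, non-centered scale update against
the likelihood — after which split potential-scale-reduction values sit
near 1 even with short chains. The PG(1, z) draws use the exact
alternating-series
rejection sampler, so the algorithm has no tuning parameters and no
asymptotic bias; a test validates the PG moments and the whole posterior
against an independent JAGS fit of the same model. By default 4 chains of
500 warmup iterations are run and exactly 1000 post-warmup draws are
pooled; split potential-scale-reduction is reported for the intercept and
all scale parameters, with a warning (not a failure) above 1.05. All
randomness funnels through one seed.

Runtimes are modest: roughly 4 s for 600 total iterations at 20,000
births with 24 columns and 300 clusters on one core, and about 8 s for the
full 176-column four-way-interaction design at 2,000 births.

## Equity statistics

All equity quantities are computed once per posterior draw, giving each
statistic a posterior mean and an equal-tailed 95% interval (the interval
type is a package choice; "significant" means the interval excludes the
null).

* **NPD** — the fraction of observed deaths outside the poorest quintile.
  Under perfect equity it is 80% by construction; a pro-poor gradient
  pushes it lower. It needs no model, only the quintiles.
* **ANOVA \(R^2\)** — per draw \(s\),
  \(R^2(s) = \mathrm{SS}_{between}/\mathrm{SS}_{total}\) of the risks
  \(p_i^{(s)}\) across a grouping (wealth quintile by default). Computed
  on the probability scale, because the quantity of interest is variance
  in *risk*, not in log-odds; a `scale = "logit"` flag offers the
  alternative. Degenerate draws with zero total variance contribute
  \(R^2 = 0\).
* **Targeting** — the observed death rate among the \(\lfloor qN \rfloor\)
  births with the highest risk in a draw, versus the death rate among the
  \(\lfloor qN \rfloor\) lowest-ranked by wealth, with
  \(\mathrm{gain} = (\mathrm{HR} - \mathrm{Poor})/\mathrm{Poor} \times
  100\). Ties at the cutoff are broken stably by table position (and
  counted); both a per-draw distribution and a posterior-mean-ranking
  point version are reported, since either convention is defensible. Only
  ranks matter, so the gain is invariant to monotone transformations of
  the risk draws.
* **Group comparisons** — per draw, the top-\(q\) high-risk set versus the
  rest: odds ratios of prevalence for binary covariates (Haldane-Anscombe
  0.5 correction when a cell is empty, with a count of corrected draws)
  and mean differences for continuous ones.
* **Boxplot summaries** — median, type-7 quartiles, whiskers at the most
  extreme points within 1.5 IQR, outliers counted but excluded.

## The synthetic generator

`generate_survey()` draws mothers (one household each) with a cluster, a
wealth score from a configurable distribution, education, residence and an
age at first birth; births then arrive roughly two years apart starting
from a first-birth date spread over the 13 years before the survey, so the
window filter always has work to do on both sides. Outcomes are simulated
*sequentially in birth order*, which makes the prior-death indicator
endogenous: it is determined by the earlier simulated outcomes of the same
mother, exactly as it will later be reconstructed by the preprocessing
step. Death dates fall uniformly within five years of birth. The linear
predictor is built from documented covariate scales plus optional
interaction products and the cluster effect; a scenario can instead supply
`prob_fun` to define the surface directly on the probability scale.

What it emulates: arbitrary per-survey wealth-score shapes, cluster-
correlated risk, endogenous birth sequences, covariate-dependent risk with
interactions, a configurable wealth gradient including exact equity. What
it does not: DHS sampling weights and stratification, seasonality,
household structure beyond one mother per household, correlated covariates
(education is drawn independently of wealth so benchmark variance shares
stay analytic), or death-age heterogeneity beyond the binary outcome.
Passing tests therefore demonstrate correctness of the machinery and
recovery under a known truth, not robustness to every feature of real
survey data.

Fixed generator choices (made once, for realism at the scale of a typical
survey): default 4000 mothers with up to four births, 150 clusters with a
0.3 log-odds cluster standard deviation, 40% urban, age at first birth
\(N(19.5, 3^2)\) truncated to \([13, 45]\), education uniform on 0-12
years, male probability 0.512, baseline risk 8%.

### Benchmark scenarios

* `equity_scenario()`: constant risk 0.10, 200,000 single-birth mothers —
  the NPD equity benchmark. The realised NPD must sit within binomial
  noise of 80%.
* `quintile_step_scenario()`: risk 0.20 in the poorest true fifth, 0.10
  elsewhere. Analytically the NPD is \(0.8 \cdot 0.1 / (0.2 \cdot 0.2 +
  0.8 \cdot 0.1) = 2/3\), comfortably below the benchmark.
* `gradient_scenario()` / `interaction_scenario()`: a smooth negative
  wealth gradient with realistic nuisance effects; the interaction variant
  adds a prior-death-by-wealth slope partly cancelled in urban areas, so
  the elevated cell (rural, prior loss, poor) is invisible to any single
  stratifier.
* `quintile_variance_scenario(f)`: risk defined on the probability scale
  as \(p_i = p_0 + a(w_i - 0.5) + g(e_i - 6)\) with wealth rank \(w\)
  uniform and education \(e\) uniform on 0-12 and independent of wealth.
  The coefficients solve for an exact between-quintile variance share
  \(f\) of a fixed total risk standard deviation (0.04 around
  \(p_0 = 0.10\)). Risk must vary within quintiles through *modelled*
  covariates — variation the model cannot see would be smoothed away and
  the fitted \(R^2\) would drift to 1 — which is why the within-quintile
  part rides on education and within-quintile wealth rather than on
  unexplained noise.

## Validation summary

The test suite checks, among other things: exact window-edge behaviour of
the filter; the midpoint-rank formula and its monotone-invariance; the
timing rules of the prior-death indicator and its monotonicity in the
mother's history; exact representability of piecewise-linear functions on
the hinge basis; the \(\binom{8}{k}\) interaction-block counts; agreement
of the sampler with an intercept-only conjugate benchmark and with an
independent JAGS fit; per-draw ANOVA \(R^2\) equal to brute-force one-way
decompositions to \(10^{-12}\); recovery of a known between-quintile
variance share \(f \in \{0.05, 0.20\}\) to within 0.05 at 20,000 births;
near-nominal (90% ± 10 points) coverage of 90% credible intervals over 20
replicate fits; and the optimality of true-risk targeting, exhaustively on
a 12-birth toy and by simulation at 10,000 births.

Problem sizes in routine tests are deliberately moderate — 2 chains of a
few hundred draws, a few thousand births — which the sampler's exact
conditionals make sufficient; the heavy checks above run at their stated
scales.

## A worked example

```{r example, message = FALSE, warning = FALSE}
births <- generate_survey(gradient_scenario(n_births = 5000, seed = 2))
tab <- prepare_births(births)

spec <- model_spec(max_interaction_order = 2, chains = 2,
                   warmup = 300, draws_total = 500)
fit <- fit_risk_model(tab, spec, seed = 2)
risk <- posterior_risk(fit)

report <- equity_report(risk, tab, q = 0.20)
report
tidy(report)
```

```{r plots, fig.width = 6, fig.height = 3.5}
plot_risk_box(risk, tab$wealth_quintile, xlab = "wealth quintile")
```

## Known limitations

* One model per survey; no pooling across surveys or countries.
* No survey weights: samples are treated as simple random samples, though
  the stratification variables themselves are in the model.
* The wealth-rank tie rule and interval conventions are documented
  package choices where the field admits several.
* The generator's covariates are mutually independent by default, which
  is unrealistic but keeps ground-truth variance shares analytic.
* Cluster effects are exchangeable; no spatial smoothing between
  clusters.
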