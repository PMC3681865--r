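---
title: "Latent health factor index models for estuarine benthic data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent health factor index models for estuarine benthic data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

Benthic grab samples are the workhorse of estuarine biomonitoring: each grab
is sorted into the five AMBI ecological groups, from pollution-sensitive
(group 1) to first-order opportunist (group 5).  Conventional indices
collapse those counts into a score by fixed formulas.  The latent health
factor index (LHFI) instead treats the counts as *indicators* of an
unobserved site-level health variable inside one hierarchical model, so that
health scores, driver effects, and all their uncertainties come from a
single posterior.

Let $y_{gmir}$ be the count of metric $m$ (in group $g$) in replicate grab
$r$ at site $i$, and $n_{ir}$ the total number of benthic organisms in the
grab.  Metrics 1–2 form the "plus" group (positively associated with
health), metrics 3–5 the "minus" group.  Each group is modelled as a
multinomial over its metrics plus a baseline category — the *remainder* of
the grab not classified into that group's metrics:

$$ (y_{g1ir},\dots, n_{ir} - \textstyle\sum_m y_{gmir}) \sim
   \text{Multinomial}(n_{ir}, p_{g1i},\dots,p_{g0i}), $$

with generalized-logit (softmax-with-baseline) links

$$ p_{gmi} = \frac{e^{\eta_{gmi}}}{1 + \sum_{m'} e^{\eta_{gm'i}}}, \qquad
   \eta_{gmi} = \delta_g + \gamma_{gm} + s_g H_i , $$

where $H_i$ is latent site health, $s_+ = +1$ and $s_- = -1$ (the
"inverted" link for the minus group: opportunist-dominated grabs indicate
poor health), $\delta_g$ is a group fixed effect and $\gamma_{gm}$ a metric
random effect.  The two multinomials overlap in the shared remainder; that
dependence is deliberately not modelled jointly — $\delta$ and $\gamma$
absorb it crudely, and the cost of this simplification is discussed under
*Limitations*.

Identifiability choices made here: $\delta_+ \equiv 0$ (one category's
group effect must be fixed when the baseline predictor is pinned at zero;
which group is fixed is arbitrary and recorded in output metadata), and the
$\gamma_{gm}$ are mean-zero random effects with no sum-to-zero constraint —
shrinkage identifies them jointly with $\delta_-$ and $H$.

Latent health is regressed on centered abiotic covariates,

$$ H_i \sim N(\beta_0 + x_i'\beta,\ \sigma^2_{\varepsilon}), $$

optionally with a month-specific error variance (September vs October).
Covariates are transformed (natural log for depth and silt–clay fraction),
then centered at their sample means; centered interactions are products of
centered parents.  Centering constants are stored with every design and
fit, so a fitted model can score new sites on the original scale.

### The two-level extension

Salinity and distance downstream (DD) are strongly collinear (the
freshwater–seawater gradient), so in a single-level regression only one of
them can appear credible.  The two-level structure instead makes salinity a
response of DD,

$$ s_i \sim N(b_0 + b_1 d_i,\ \sigma^2_s), $$

with salinity (not DD) among the health covariates.  Substituting one level
into the other collapses the hierarchy to a single DD regression with
intercept $\beta_0 + \beta_{sal} b_0$, slope $\beta_{sal} b_1$, and total
error variance $\sigma^2_\varepsilon + \beta_{sal}^2 \sigma^2_s$
(`collapse_two_level()`).  The *variance ratio*
$\sigma^2_\varepsilon / (\sigma^2_\varepsilon + \beta_{sal}^2\sigma^2_s)$
measures how much of the collapsed error variation the implicit salinity
covariate explains: smaller is more.  Salinity is centered before both
regressions; $b_0$ is retained even though centering makes it near zero,
to keep the level's regression form intact.

### Priors

Fixed effects and regression coefficients get $N(0, 100)$ priors; every
variance gets an inverse-Gamma with unit shape and scale; unstructured
metric-effect covariance blocks get inverse-Wishart priors with identity
scale and degrees of freedom equal to the block dimension plus 1 — the
smallest integer offset that yields a proper prior with a uniform marginal
correlation, hence suitably diffuse.  For the bivariate-coefficient variant
(`model4`) the pair $(b_0, b_1)$ is jointly Gaussian with correlation
$\rho \sim \text{Uniform}(-1, 1)$; the source material truncates before
stating this prior, so the uniform choice is this package's, not asserted
as the original authors'.

Three metric-effect covariance structures are supported: `iid` (a single
$\sigma_\gamma$), `block_diagonal` (unstructured within-group blocks
$\Sigma_{++}$, $\Sigma_{--}$, zero cross-block) and `unstructured` (a full
5×5 with the cross-block).  The shipped presets `model1`–`model5` all use
`iid`, reflecting the finding that health inference is robust to the
richer structures.

## Sampling

The posterior is sampled by a purpose-built Metropolis-within-Gibbs kernel
(compiled, single-threaded, all randomness from R's RNG so a seed fixes
the output bit-for-bit):

* $H_i$, $\delta_-$ and each $\gamma_{gm}$: adaptive random-walk
  Metropolis (batch-wise step adaptation toward 0.44 acceptance, active
  only during burn-in so the post-burn-in kernel is fixed).
* $(\beta_0, \beta)$, $\sigma^2_\varepsilon$, $\sigma^2_\gamma$ or the
  $\Sigma$ blocks, $(b_0, b_1)$, $\sigma^2_s$: exact conjugate Gibbs draws
  (Gaussian, inverse-Gamma, inverse-Wishart via Bartlett decomposition).
* $\rho$: griddy Gibbs on a 199-point grid over $(-0.99, 0.99)$.

Two exact Gibbs *recentering* moves are essential.  The likelihood is
invariant along two ridges: $(\delta_- + c,\ \gamma_{-} - c)$, and
$(\gamma_{+} + c,\ H - c,\ \delta_- - c,\ \beta_0 - c)$ (the latter also
leaves every latent-regression residual unchanged).  Componentwise updates
diffuse along these ridges extremely slowly — interval-BGR values above 6
in early experiments; sampling the shift $c$ from its exact Gaussian
conditional restores mixing (max BGR ≈ 1.01 at a few thousand iterations).
This is the hierarchical-centering idea applied to this model's specific
non-identified directions.

Burn-in `"auto"` discards the first half of each chain and then *verifies*
max interval-BGR < 1.1; on violation the fit reports non-convergence
rather than silently extending.  Stored trace exports are thinned (default
100); summaries always use every post-burn-in draw.

## Diagnostics and reporting

* **BGR**: the interval-based Brooks–Gelman–Rubin variant — pooled central
  80% interval width over mean within-chain width, on successive windows —
  plus the classical ratio-of-variances PSRF (`bgr_scalar()`).  Interval
  widths use inverse-CDF (type-1) quantiles, which are invariant to
  pooling identical chains, so "identical chains give exactly 1" holds to
  the last bit.  The 80% width is a package choice; the width used for the
  original three-curve plots is not recoverable.
* **Credible intervals**: equal-tailed, type-7 sample quantiles; a slope is
  flagged "credible" when its interval excludes 0.  No p-values and no
  multiplicity adjustment, matching the CI-only screening rule.
* **DIC**: deviance focused on the *observed metrics* (plus the salinity
  response for two-level fits), conditional on the latent quantities,
  plugged in at their posterior means for $D(\bar\theta)$ — the common
  BUGS-style conditional DIC.  Marginal-likelihood DIC is out of scope.
* **Health table**: per-site posterior mean/median/interval of $H_i$, ranks
  by posterior mean (ties broken by site order), and interval-overlap
  counts.  Health is an analysis-of-covariance quantity: only relative
  comparisons are meaningful.

## The synthetic-data generator

The generator emulates the study design the analysis assumes: 18 sites (13
September, 5 October — sites 4–8 are the October, upper-channel block),
2–3 replicate grabs per site (3 at odd sites, 2 at even), per-grab totals
uniform on 150–400 (the real totals are not published; this is a scenario
parameter), the fixed 18-site DD gradient, salinity generated from the
salinity-on-DD line with noise scaled so the realized DD–salinity
correlation targets 0.88, and log-depth / log-silt–clay drawn with weak
target correlations to DD (0.16 and −0.47).

Counts are generated per grab in two stages: plus-group counts (and the
grab remainder) from the plus multinomial; then minus-group counts
allocated *within* that remainder using the minus probabilities
renormalized by the plus-remainder probability, $q_m = p^-_m / p^+_0$.
When the generating composition is feasible ($\sum_m p^-_m \le p^+_0$)
this construction makes each group's counts exactly multinomial at its own
link probabilities, so the fitted two-multinomial pseudo-likelihood is
marginally correctly specified and only the shared-remainder dependence is
ignored.  Infeasible compositions are capped (renormalized to exhaust the
remainder), which distorts the minus margins — the generator's defaults
avoid that regime.

Default generating values sit on the scale of typical estuarine LHFI
posteriors: slopes 0.4–0.8 ($\beta_{dd} = 0.4$, $b_1 = 0.77$), error
standard deviations 0.6–1.1 ($\sigma_\varepsilon = 0.7$; $\sigma_s$
derived from the 0.88 correlation target, ≈ 0.62).  The metric-effect
defaults $\gamma = (-0.9, -1.3, 0.2, -0.2, 0)$, $\delta_- = -1.1$ were
chosen for *compositional feasibility*: at average health they put ≈ 40%
of organisms in the sensitive/indifferent groups, ≈ 50% in the
tolerant-to-opportunist groups and ≈ 10% unclassified.  (Mean-zero plus
-group effects would instead assert that each group alone claims most of
the grab — the two margins would sum past 100%, and no dataset can follow
such a "truth".)

What the generator does **not** emulate: spatial autocorrelation in
covariates or errors, overdispersion beyond multinomial sampling,
taxonomic misclassification, ITI trophic-group counts, or any real
ecological structure beyond the modelled hierarchy.  Passing recovery
tests therefore show that the fitting machinery inverts the assumed
generative process at the study's size and noise levels — not that the
model is adequate for any particular field dataset.

## Numerical choices

* Softmax links guard against overflow by max-subtraction; finite
  predictors never yield NaN.
* Non-positive-definite covariance proposals raise an R error (an invalid
  proposal, not a crash); inside the sampler the conjugate updates keep
  blocks SPD by construction.
* Log of a non-positive covariate value is an input error, raised before
  any fitting.
* Rank ties in the health table break by site order (`ties.method =
  "first"`).
* Problem sizes used by the shipped checks (chosen to give stable Monte
  Carlo behaviour at interactive run times): fits use 2 chains of
  4\,000–12\,000 iterations with 1\,500–4\,000 burn-in; recovery studies
  use 40 simulate–fit cycles (single-level) and 10 (two-level); the
  collapsed-model Monte Carlo check uses $10^5$ draws.

## Limitations

* Health values are relative; without a pre-identified very healthy or
  very degraded reference site the absolute scale has no interpretation.
* The two overlapping multinomials double-count the shared remainder;
  posterior spread for observation-level parameters is accordingly a
  little optimistic, and $\sigma_\varepsilon$ recovers with a mild upward
  tilt (its simulate–fit coverage is ≈ 0.88–0.95 at the default scenario,
  not the nominal 0.95).
* $\delta_-$ and the within-group means of $\gamma$ are only
  prior-identified (the likelihood ridges above); their individual
  posteriors should not be over-interpreted.
* With 18 sites the per-site health intervals mutually overlap at 95%;
  the design supports ranking tendencies and driver inference, not sharp
  site discrimination.
* No point-referenced spatial model is included; DD is the only spatial
  structure, by design.
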