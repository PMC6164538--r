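---
title: "Count models for zero-heavy census-block surveillance data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Count models for zero-heavy census-block surveillance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small-area disease surveillance often yields one count per areal unit: the
number of cases observed in a census block, together with a population-at-risk
denominator and a handful of block-level covariates.  Such counts are
typically *rare* (many zeros), *overdispersed* (variance several times the
mean), and *spatially structured*.  The motivating setting for this package
is childhood lead poisoning screening: per census block, the number of
children whose blood lead level reached the clinical threshold, with the
number of screening tests as the offset and three covariates — mean housing
construction year, log mean taxable housing value (in $1000s), and log soil
lead concentration (ppm).

`blockcount` fits and compares four model families for this kind of table,
each optionally with a Gaussian random intercept per block:

* **Poisson**: $Y_i \sim \mathrm{Pois}(\mu_i)$, $\log \mu_i = x_i^\top\beta +
  \log N_i + \gamma_i$, $\gamma_i \sim N(0, \sigma^2)$.
* **Negative binomial (NB2)**: $\mathrm{Var}(Y_i \mid \gamma_i) =
  \mu_i(1 + \kappa\mu_i)$, with dispersion $\kappa \ge 0$; $\kappa \to 0$
  recovers the Poisson.
* **Poisson / NB hurdle**: a logistic model for $p_i = P(Y_i = 0)$,
  $\mathrm{logit}\, p_i = x_i^\top\alpha + \gamma_{0i}$, combined with a
  zero-truncated Poisson or NB for the positive counts.  All zeros are
  treated as sampling zeros (every block in the table was screened), which is
  what distinguishes the hurdle from a zero-inflated mixture; zero-inflated
  models are deliberately out of scope.

The offset coefficient is fixed at 1, so the models describe *rates* per
screening test.  The two hurdle random-effect streams ($\gamma$, $\gamma_0$)
are independent; a correlated version is out of scope.

### Orientation of the logistic part

The logistic part models the probability of a **zero** ($p_i = P(Y_i = 0)$).
Under the opposite convention (modelling $P(Y_i \ge 1)$, which some software
uses by default) every $\alpha$ coefficient flips sign.  Published
coefficient tables for this class of analysis are often printed under the
opposite orientation: taken at face value under ours they would imply mostly
*positive* counts in data described as zero-heavy.  The synthetic defaults
therefore carry the sign-flipped logistic coefficients.

## Estimation

Each block contributes one observation and one latent intercept, so the
marginal likelihood is a product of one-dimensional integrals
$$ L_i = \int f(y_i \mid x_i^\top\beta + \log N_i + t)\,
   \varphi(t; 0, \sigma^2)\, dt. $$
These are evaluated by **adaptive Gauss–Hermite quadrature**: per block the
integrand is mode-centred (damped Newton with analytic first derivatives) and
curvature-scaled, then integrated with `quadrature_points` nodes (default 7;
1 node is the Laplace approximation).  Posterior modes are cached across
optimizer iterations as warm starts.  Convergence of the rule was measured on
the shipped fixture: the 7-node total log-likelihood is within
$2.6\times10^{-4}$ of the 25-node limit over 1,393 blocks, and 15 vs 25 nodes
agree to $5\times10^{-8}$.

The Bernoulli factor of the hurdle models is always integrated with at least
25 nodes regardless of the setting: its integrand is wide relative to its
curvature at the mode and its likelihood surface is a flat ridge in
$(\alpha, \sigma^2_0)$, so residual quadrature error at low node counts can
manufacture spurious interior optima (we observed exactly this at 7 nodes).
Nodes are nearly free there, accuracy is not.

Hurdle likelihoods factorize exactly into the Bernoulli factor (all blocks)
and the zero-truncated factor (positive blocks), because the two intercept
streams are independent; the package maximizes the two factors separately,
which *is* the joint maximum-likelihood estimate, and exposes the joint
marginal log-likelihood through `marginal_loglik()` so the factorization can
be verified numerically.

Numerical choices:

* variance components and the dispersion are optimized as $\log\sigma^2$,
  $\log\kappa$ (unconstrained search, natural-scale reporting with
  delta-method standard errors);
* covariates are centred internally — construction years near 1900 would
  otherwise make the intercept column of the design numerically collinear
  with them — and estimates and covariances are mapped back exactly;
* probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside logarithms;
* the NB log-pmf switches to its Poisson limit below $\kappa = 10^{-6}$,
  where the explicit log-gamma form starts losing precision;
* zero-truncated pmfs compute $\log(1 - f(0))$ through `expm1`, so means far
  below 1 do not cancel catastrophically;
* starting values come from the corresponding fixed-effects GLM fits, with
  $\sigma^2 = \kappa = 0.5$;
* convergence is declared on a finite-difference gradient max-norm below
  `grad_tol` scaled by $|\log L|$ (an absolute $10^{-4}$ would sit below the
  finite-difference noise floor at $n \approx 1400$), with restarts through a
  second optimizer when a warm start trips the step-size criterion early;
* a dispersion or variance component that collapses to the boundary
  ($\hat\kappa$ or $\hat\sigma^2 < 10^{-4}$) is frozen out of the observed
  information: its own SE is reported `NA` instead of letting one flat
  log-scale direction void every standard error.

Standard errors are Wald, from the inverse of the numerically differentiated
observed information; $p$-values in serialized fits are two-sided normal.

## Prediction

`predict_expected_counts()` offers two modes.  *Marginal* integrates the
intercepts out — for the log link this multiplies the fixed-effect mean by
$e^{\sigma^2/2}$, and hurdle means compose as
$E[1 - p_0] \cdot E[\mu / (1 - f(0;\mu))]$ with each expectation taken by
quadrature over its own intercept distribution.  *Conditional* plugs in the
per-block empirical-Bayes modes and is defined only for fitted blocks; a
held-out block has no estimated intercept, which is why the jackknife uses
marginal predictions.

## Validation battery

`jackknife()` refits the model $n$ times leaving one block out (warm-started
from the full fit; a seeded subsample of leave-outs is available for
desk-scale runs) and predicts each held-out block marginally.  From these
predictions: mean prediction error (MPE), mean absolute error (MAE), a
frequency-binned Pearson $\chi^2$ (predictions rounded into count categories
0–4 and 5+ by default; categories with predicted frequency below 1 merge
upward), and the Spearman rank correlation between observed and predicted
counts.  Rounding is the default because the classical presentation
aggregates rounded predictions, but note its artifact: marginal hurdle means
cluster just above 0.5 and round to 1, so a *better* model can post a *worse*
rounded $\chi^2$.  `predicted_category_probs()` plus the `predicted_probs`
argument of `frequency_chi2()` give the rounding-free alternative (expected
category frequencies as sums of model-implied category probabilities), under
which the generating model reliably beats a misspecified one.
`compare_models()` assembles the per-family table (−2 logL, AIC, parameter
counts, the validation metrics) and flags the AIC winner and whether its lead
exceeds 2.

`morans_i()` implements Moran's I with binary or row-standardized weights and
normal-approximation inference ($E[I] = -1/(n-1)$, two-sided $p$).  Lattice
contiguity (rook/queen) and GAL files are the two supported weight sources.

## The synthetic world

No surveillance data ship with the package; every analysis is exercised on a
calibrated generator (`sim_config()`, `simulate_block_data()`).  Its defaults
*are* the published summary of the motivating dataset: 1,393 blocks; offsets
with mean 31.05 and variance 430.03 (negative-binomial integers floored at 1;
the floor shifts the moments by under 0.2%); covariates with raw-scale means
1923 / \$58,445 / 185.8 ppm, variances 308.6 / 5.67×10⁸ / 12,660, and
pairwise Pearson correlations 0.35 (year–tax), −0.54 (year–soil), −0.33
(tax–soil); NB-hurdle coefficients at the published scale with the logistic
signs flipped to our $P(Y=0)$ orientation.

Covariates are drawn through a **Gaussian copula**: the year with a normal
margin, tax value and soil lead with lognormal margins moment-matched on the
raw scale, and copula correlations adjusted in closed form so the raw-scale
Pearson correlations hit their targets.  A raw-scale Gaussian (the obvious
alternative) puts ~5% of soil draws at or below zero; resampling or clipping
them truncates the left tail and attenuates the year–soil correlation by
about 0.02 — enough to eat the ±0.05 calibration band — while the lognormal
margins also reproduce the published skew (medians below means, strictly
positive minima).

Random intercepts are iid normal by default; a proper conditional
autoregressive (CAR) option (`spatial_smoothing` $= \rho \in [0,1)$,
precision $\propto D - \rho A$, rescaled so marginal variances average
$\sigma^2$) exists solely so that spatial diagnostics have signal to detect —
the *fitted* models always use iid intercepts.  Counts are drawn by the
configured family, positives by inverse-CDF sampling from the zero-truncated
distribution.  All randomness flows through one master seed with
deterministic per-stage sub-streams, so stages can be regenerated
independently.

`make_paper_like_dataset()` ships the canonical fixture: 1,393 blocks,
NB-hurdle process, with the two intercepts tuned once ($\alpha_0 = -26.1$,
$\beta_0 = 22.6$) so the realized counts land in the documented calibration
band (≥ 60% zeros, mean in [0.4, 1.0], variance/mean > 2).  The zero
fraction of the real data was never published; the ≥ 60% band is a modelling
choice consistent with the qualitative description of the frequency
distribution, not a published value.

What a green test on this world does *not* establish: the generator draws
covariates independently across blocks (no spatially smooth covariate
fields), uses exactly the assumed parametric families, and has no geocoding
error, no interpolation error in the soil surface, and no temporal mismatch
between data sources — all of which real surveillance tables have.

## Known limitations

Two published phenomena are **not** reproducible in this stated world, and
the corresponding acceptance tests are deliberately left failing rather than
weakened; both trace to the same structural fact that every block contributes
a single observation.

1. *Hurdle coefficient recovery.*  With one Bernoulli observation per block,
   the marginal likelihood of the logistic part depends on $(\alpha,
   \sigma_0^2)$ almost only through a common rescaling: as $\sigma_0 \to
   \infty$ with $\alpha \propto \sigma_0$ the model tends to a probit-type
   curve, so the profile log-likelihood over $\sigma_0^2 \in [0, 20]$ spans
   only ~0.4 units.  The MLE lands at ridge extremes — $\hat\sigma_0^2$
   collapses to 0 (attenuating $\hat\alpha$ ~10–15%) or runs large
   (inflating it far more) — and mean relative biases of 20–70% at
   $n = 1393$ follow, even though 3-SE Wald coverage is simultaneously
   conservative (the same flatness inflates the SEs).  In the truncated
   part, $\kappa$ (within-block extra variance) and $\sigma^2$ (between-block
   variance) are nearly interchangeable for singleton blocks, with analogous
   consequences.  This is the estimator's genuine small-sample behaviour:
   quadrature was verified against `stats::integrate` to $10^{-5}$ per
   observation, the truncated sampler against its pmf, and estimates are
   invariant to 7 vs 15 nodes.

2. *Residual Moran's I reduction.*  For a singleton-block Poisson model the
   empirical-Bayes mode equation gives $y_i - \hat\mu_i(\hat\gamma_i) =
   \hat\gamma_i / \hat\sigma^2$ exactly: conditional residuals are
   *proportional to the estimated intercepts*, which carry precisely the
   spatial field the intercepts absorbed.  Adding random effects therefore
   cannot whiten conditional residuals here (empirically their Moran $Z$ is
   usually slightly larger than the no-RE model's), and marginal or
   Pearson-scaled variants change the picture by at most a few percent.  The
   often-reported "random effects removed the residual spatial
   autocorrelation" pattern requires repeated observations per unit, spatial
   structure carried by observed covariates, or an explicitly spatial prior
   on the intercepts — none of which are part of this model class.

Model selection between the Poisson hurdle and NB hurdle (acceptance
criterion 5) is weakened by the same $\kappa$/$\sigma^2$ confounding: on
NB-hurdle data the Poisson hurdle with a larger $\hat\sigma^2$ tracks the NB
hurdle within a few AIC units, so the generating family wins a modest
majority rather than the required 70% of replicates.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `quadrature_points` | 7 | adaptive GH nodes; 1 = Laplace; binary hurdle factor always uses ≥ 25 |
| `rel_tol` | 1e-8 | relative log-likelihood change at which the optimizer stops |
| `grad_tol` | 1e-4 | gradient max-norm per unit of \|logL\| for the convergence flag |
| `kappa` | 1.259 | NB2 dispersion of the generator (published NB-hurdle scale) |
| `sigma2`, `sigma2_zero` | 0.346, 0.687 | intercept variances, count and logistic parts |
| `spatial_smoothing` | 0 | CAR dependence of simulated intercepts (generator only) |
| `offset_mean`, `offset_var` | 31.05, 430.03 | screening-test moments |
| jackknife `subsample` | `NULL` (full) | seeded number of leave-outs for desk-scale runs |

## Reproducibility

Every pipeline artifact embeds the package version, a hash of the
configuration, and the master seed.  `blockcount simulate | fit | validate |
pipeline` expose the same functionality from the command line
(`inst/cli/blockcount`); configuration files are JSON.
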