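---
title: "Methods: spatial zero-inflated Poisson abundance mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial zero-inflated Poisson abundance mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipmap)
```

## The model and its assumptions

`zipmap` models a count survey $Y_1, \dots, Y_n$ at planar locations
$s_1, \dots, s_n$ as a zero-inflated Poisson mixture. With prevalence
$\pi_i$ (probability of presence) and intensity $\mu_i$ (Poisson mean given
presence),

$$P(Y_i = 0) = (1 - \pi_i) + \pi_i e^{-\mu_i}, \qquad
  P(Y_i = y) = \pi_i \frac{e^{-\mu_i}\mu_i^y}{y!} \;\; (y \ge 1).$$

Zeros therefore arise from two distinct processes: *structural* zeros
(unsuitable conditions, probability $1-\pi_i$) and *Poisson* zeros (suitable
conditions, nothing caught in the core). A note on conventions: the mixture
is often written with a parameter attached to the zero mass; this package
consistently parameterizes with the **prevalence** $\pi$ — the probability
that the Bernoulli process yields presence — and forms the structural-zero
weight as $\omega = 1-\pi$ internally. The expected count before
conditioning on presence, $\pi\mu$, is called the *unconditional intensity*
and is the quantity an abundance map ultimately shows.

Both parameters are driven by latent Gaussian signals (generalized linear
spatial models):

$$\mathrm{logit}(\pi_i) = x_{B,i}^\top \beta_B + \eta_{B,i}, \qquad
  \log(\mu_i) = x_{P,i}^\top \beta_P + \eta_{P,i},$$

with $\eta_B$ and $\eta_P$ **independent** zero-mean stationary isotropic
Gaussian processes: the joint covariance of the two error vectors is block
diagonal by assumption, and the generator builds it that way. Each process
has covariance

$$C(h) = \sigma^2 \rho(h; \phi) + \tau^2 \, 1(h = 0),$$

with partial sill $\sigma^2$, range $\phi$ (meters), nugget $\tau^2$, and
$\rho$ either the spherical correlation
$1 - 1.5(h/\phi) + 0.5 (h/\phi)^3$ for $h \le \phi$ (0 beyond) or the
exponential $e^{-h/\phi}$. The nugget is interpreted as a spatially
uncorrelated component of the *latent signal* (micro-scale variation at
lags below the grid spacing plus measurement-like noise on the latent
scale). Two consequences, chosen deliberately and used consistently: the
nugget contributes to the prediction variance at unsampled sites
($\sigma^2 + \tau^2 - c^\top C^{-1} c$), and it enters the diagonal of
every covariance matrix, which also keeps the linear systems well
conditioned.

## Calibration

**Step 1 — nonspatial fit.** `fit_zip_ml()` maximizes the mixture
likelihood with both error terms dropped, over $(\beta_B, \beta_P)$ jointly
by BFGS with the analytic gradient, started from a logistic regression on
the positive-count indicator and a Poisson regression on the positive
counts. The optimized log-likelihood is reported and is never below the
starting value.

**Step 2 — zero classification.** Each observed zero is classified as
structural with probability equal to the ratio of the structural-zero
probability to the total zero probability,
$\omega_i / (\omega_i + (1-\omega_i)e^{-\mu_i})$, evaluated at the fitted
values. The ratio is already a probability, so it is used directly. A zero
classified as Poisson keeps presence indicator 1 and joins the Poisson data
set; positive counts always do. The classification is stochastic and seeded;
its effect on the final maps is precisely what `replication_stability()`
measures.

**Step 3 — MCMC + MCML per submodel.** Conditional on data and current
parameters $\theta_0$, `mala_sample()` simulates the latent signal by a
Metropolis-adjusted Langevin (Langevin–Hastings) chain. The chain runs on a
whitened parameterization $z = A^{-1}(S - X\beta)$ with $C = AA^\top$, so
the prior of $z$ is standard normal and a single scalar step size is
adequate; proposals are
$z' = z + \tfrac{h}{2}\nabla \log p(z) + \sqrt{h}\,\varepsilon$. The step
size is adapted during burn-in by stochastic approximation
($\log h \leftarrow \log h + t^{-0.6}(\alpha_t - \alpha^*)$) toward a
target acceptance rate of $\alpha^* = 0.55$, close to the optimal rate for
Langevin samplers, then frozen so the retained draws satisfy detailed
balance. Full-scale defaults mirror practice for this model family:
100,000 iterations for the Poisson process, 50,000 for the Bernoulli,
burn-in 100, thinning 100; convergence evidence (acceptance rate, lag-1
autocorrelation of retained draws, Geweke z-scores computed with AR-based
spectral variance estimates) is emitted as a machine-readable report by
`run_report()` rather than plots only. The full-scale burn-in of 100
presumes a pre-tuned step size; adaptive runs should use a longer burn-in
(the desk-scale profiles use 300–2000) so the adaptation has settled before
it is frozen.

Given draws $S_1, \dots, S_J$ simulated under $\theta_0$, the likelihood of
any $\theta$ relative to $\theta_0$ is approximated by Monte Carlo maximum
likelihood: $L_m(\theta) \approx J^{-1}\sum_j f(S_j\mid\theta) /
f(S_j\mid\theta_0)$, where $f$ is the exact multivariate-normal density of
the signal. `mc_loglik()` computes its log via log-sum-exp and reports the
effective sample size of the implied importance weights (a degeneracy
warning below ESS 5). `maximize_mcml()` optimizes over
$(\beta, \log\sigma^2, \log\tau^2, \log\phi)$ — the log scale keeps the
variance parameters positive and the surface smooth — by BFGS followed by a
Nelder–Mead polish, keeping whichever is better. Because the approximation
is trustworthy only near $\theta_0$, `calibrate_submodel()` re-centers:
it alternates sampling and maximization (default three cycles) and records
the per-cycle estimates so stabilization can be inspected. Pilot runs at
desk scale show the first cycle travels far and later cycles shrink on
average, while per-cycle jitter from the Monte Carlo surface remains; this
is why the default is iterate-and-inspect rather than iterate-to-strict-
convergence.

Initial values for cycle 1 (no rule is standard): $\beta$ from the
nonspatial fit, $\sigma^2 = \tau^2 =$ half the deviance-residual variance
of a nonspatial GLM (an even split of the unexplained variance between
structured and unstructured components), and $\phi =$ a quarter of the
domain diameter.

**Model comparison.** Two covariate sets (a minimal "small" and a richer
"large" model) are compared by the difference in twice the log-likelihood
against one half of the $\chi^2_{1-\alpha}$ quantile with degrees of
freedom equal to the number of extra covariates
(`model_comparison_threshold(0.05, 5)` = 5.5).

## Prediction

For each retained signal realization, `simple_krige_external_drift()`
predicts at every grid node with the drift $x(s)^\top\hat\beta$ treated as
known (plug-in trend — this is what distinguishes *simple* kriging with an
external drift from universal kriging, which would re-estimate the trend
within the predictor) and kriges the residual. Predictions are
backtransformed by a second-order Taylor expansion of the inverse link:
$e^{\hat S}(1 + v/2)$ for the log link and
$p + p(1-p)(1-2p)\,v/2$, $p = \mathrm{logistic}(\hat S)$, clamped to
$[0,1]$, for the logit link; at $v = 0$ both reduce to the plain inverse
link. `build_maps()` averages 100 realizations (default) per process
pixel-wise into prevalence and intensity maps. The unconditional-intensity
map is stored in both defensible forms — the product of the two mean maps
(the headline map) and the mean of the per-realization products — because
the two differ slightly whenever prevalence and intensity realizations are
averaged separately; the coefficient-of-variation map is always computed
from the per-realization products, since it is meant to show Monte Carlo
uncertainty of the expected count.

Covariates measured at points rather than everywhere are carried to the
grid by inverse distance weighting (`idw_interpolate`), with power 2 and 12
neighbors as defaults (the method is standard; no parameter values are
canonical, and these are the common GIS defaults).

## Validation

`loo_predict()` computes leave-one-out kriging predictions through the
precision matrix ($\hat r_i = r_i - (Qr)_i / Q_{ii}$, variance $1/Q_{ii}$),
which is algebraically identical to re-solving each reduced system and is
tested against that from-scratch oracle. The held-out signal is the
per-location posterior-mean signal — a reproducible, seed-free choice;
holding out individual realizations is equally defensible but noisier.
Prevalence predictions thresholded at 0.5 are cross-tabulated against raw
presence ($\text{count} > 0$) by default — the only classification-seed-
free observed class; validating against the stochastic indicator instead
is available via `observed = "indicator"`. Intensity errors (ME, MSE) are
computed against counts on the Poisson subset, and unconditional-intensity
errors against raw counts at all locations.

## The synthetic-data generator

`generate_design()` reproduces the survey geometry: an $r \times c$ grid at
500 m spacing plus supplementary points exactly 250 m from parent nodes
drawn without replacement, direction uniform on $\{+x, -x, +y, -y\}$. A
direction that would duplicate an existing location is re-drawn (duplicates
would make kriging systems singular; how out-of-area offsets were handled
in the original survey is not documented, so re-drawing is this package's
choice). `simulate_covariates()` draws stand-ins for silt content, median
grain size and altitude as Gaussian random fields by exact covariance
factorization (no approximation — intended for desk-scale $n$), scales all
columns to mean 0, SD 1 over the design locations, and adds squared terms
and scaled coordinates so quadratic trend models can be fitted directly.
`simulate_survey()` draws the two signals from their exact joint MVN,
presence from the logistic signal and counts from the exponentiated one;
with a prediction grid supplied, the fields are simulated jointly at nodes
and stations so the true $\pi\mu$ surface is available for map-recovery
checks.

What the generator does *not* emulate: real bathymetry or sediment
structure, anisotropy, preferential sampling, detection error beyond the
Poisson-zero mechanism, and temporal change. Passing recovery tests on
these simulations therefore demonstrates the correctness and internal
consistency of the estimation and mapping machinery under the model's own
assumptions — not that the model fits any particular real ecosystem.

## Numerical choices and problem sizes

- Covariance factorizations use dense Cholesky; duplicate coordinates are
  rejected up front. The degenerate $\sigma^2 = 0$ case (simulation only)
  bypasses factorization.
- The MALA initial step is $2.4^2 / n^{1/3}$ (optimal-scaling heuristic),
  adapted only during burn-in. A post-adaptation acceptance rate outside
  (0.05, 0.95) triggers a convergence warning.
- `mc_loglik` evaluates all draws through one factorization per $\theta$;
  the optimizer treats failed factorizations as a large penalty rather than
  an error, so the search simply backs away from invalid regions.
- Geweke's spectral variance at frequency zero uses an AIC-selected AR fit,
  reducing to the sample variance at order 0.
- The test-suite and acceptance problem sizes are deliberately desk-scale
  (n = 150–300 stations, 1,200–12,000 MCMC iterations, 150–500 retained
  draws, 100–200 grid nodes, 10-seed replicate loops), chosen so that the
  full suite exercises every stage of the pipeline — including ten
  end-to-end runs — in minutes on a single core. The `"full"` profile
  carries the full-scale settings.

## Known limitations

- The Monte Carlo likelihood surface degrades far from $\theta_0$
  (importance-weight degeneracy); estimates from a single cycle started far
  from the truth are unreliable, which is exactly why calibration
  re-centers over cycles.
- Variogram parameters (especially $\tau^2$ vs $\sigma^2$, and $\phi$) are
  weakly identified at small $n$; desk-scale recovery is accurate only to a
  factor-of-two standard.
- Dense linear algebra limits surveys to a few thousand stations per
  factorization; the full-scale profile is compute-intensive by design.
- No anisotropy, no Matérn family, no cross-covariance between the
  Bernoulli and Poisson processes, and no negative-binomial or Hurdle
  variants of the mixture.
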