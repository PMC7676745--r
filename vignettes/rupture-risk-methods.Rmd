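---
title: "Probabilistic rupture-risk assessment: models, assumptions and numerics"
author: "aaarisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic rupture-risk assessment: models, assumptions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaarisk)
```

## The problem

An abdominal aortic aneurysm (AAA) ruptures when the local wall stress
exceeds the local wall strength. With the maximum von Mises stress
$\sigma^{\max}_{vm}$ as the stress summary and a spatially constant
strength $\sigma_\gamma$, rupture is the event
$\sigma^{\max}_{vm} > \sigma_\gamma$. The quantities that decide this
event — wall thickness $t$, the stiffness parameters $\alpha,\beta$ of
the wall's hyperelastic strain energy
$\Psi = \alpha(\bar I_1 - 3) + \beta(\bar I_1 - 3)^2$, and the strength
$\sigma_\gamma$ — cannot be measured in a living patient. They are
therefore treated as a random vector
$\Theta = (t, \alpha, \beta, \sigma_\gamma)$ whose distribution is
predicted from non-invasive clinical data, and the package's central
output is the probability of rupture

$$\mathbb{P}_{\mathrm{rupt}}
  = \mathbb{E}_{p(\log\Theta)}\!\left[\mathbf{1}_{\log\sigma^{\max}_{vm}(\theta) > \log\sigma_\gamma}\right],$$

estimated by Monte Carlo over the joint (correlated) predictive
distribution. Two established comparators are computed alongside: the
deterministic stress/strength ratio RPI, and the PRRI, which integrates
over independent cohort-based distributions of $t$ and $\sigma_\gamma$
only. The joint formulation contains the PRRI as the special case of an
independent product density.

## Predicting wall properties: multi-output Gaussian process

`mgp_fit()` models the log-properties jointly as

$$\log\Theta(\xi) \sim
  \mathcal N(\mu_{\log\Theta}(\xi), \Sigma_{\log\Theta}(\xi)),$$

where $\xi$ are eight normalized clinical features (maximum AAA
diameter, maximum thrombus thickness, AAA length, subrenal diameter,
thrombocytes, hemoglobin, MCH, MCV). All four outputs share one
covariance function
$k(\xi,\xi') = \zeta_1 + \zeta_2\langle\xi,\xi'\rangle +
\zeta_3 e^{-\zeta_4\|\xi-\xi'\|^2}$; between-output covariance is the
coregionalization matrix $\Omega = LL^\top$ with a free lower-triangular
$L$, and each output carries independent noise $S_{dd}$. The stacked
covariance $\Omega \otimes K + S \otimes I_n$ is never formed densely:
it is factorized through the eigensystems of $K$ and of
$S^{-1/2}\Omega S^{-1/2}$, which reduces every likelihood evaluation,
solve and determinant to $O(n^3 + n^2)$ instead of $O((4n)^3)$. The
test suite verifies likelihood, prediction and entropy against dense
`kronecker()`-assembled oracles to $10^{-8}$.

Choices that matter:

* **Logs are natural logs**; entropies are in nats.
* **Centring.** The prior is zero-mean; the fit centres each log output
  on its training mean and restores the centre in predictions. The
  constant kernel term $\zeta_1$ could absorb the means in principle,
  but centring keeps the optimization well-scaled.
* **Optimization.** The 18 hyperparameters (positives
  log-transformed) are fitted by multi-start L-BFGS-B (default 10
  seeded starts). A small jitter, $10^{-8}$ times the mean kernel
  diagonal, conditions $K$; it is configurable and reported.
* **Identifiability.** The noise $S$ and the diagonal of $\Omega$ are
  separated mainly by patients contributing several tissue samples at
  identical features (true of the motivating database, and of the
  synthetic generator). With one sample per patient and a
  near-diagonal kernel the split is weakly identified, and recovered
  $\Omega$ correlations inherit that uncertainty; the recovery test
  therefore replicates the simulation and checks the entrywise median.
* **Baselines.** `model1_cohort_lognormal()` is the cohort baseline:
  independent log-normals with population moments, identical for every
  patient. `mgp_fit(kind = "model2")` freezes the off-diagonal of $L$,
  giving independent GPs with a shared kernel. `loocv_benchmark()`
  scores all three by leave-one-patient-out PSMSE (standardized square
  error, pluggable because conventions differ between groups) and the
  patient predictive entropy
  $\mathbb H = \tfrac12\log\!\big((2\pi e)^4 |\Sigma|\big)$.

## The forward model

The stress map $\sigma^{\max}_{vm}(t,\alpha,\beta)$ is a plug-in
contract: any callable returning a positive stress in kPa can be
registered, including an external finite-element solver (field-valued
solvers should reduce to a scalar summary such as a high percentile of
the von Mises field before returning). The packaged desk-scale model is
a statically determinate **membrane balloon**: a sphere of reference
radius $R_0$ (default 25 mm) and thickness $t$, the aneurysm-wall
strain energy above, equibiaxial stretch $\lambda$ with
$I_1 = 2\lambda^2 + \lambda^{-4}$, and equilibrium
$P = (t/R_0)\,\lambda^{-2}\hat w'(\lambda)$. The load is the mean
arterial pressure MAP $= p_{\mathrm{sys}}/3 + 2p_{\mathrm{dia}}/3$
(defaults 121/87 mmHg, MAP 98.33 mmHg) raised by 50 % and converted at
1 mmHg = 0.133322 kPa. The smallest root $\lambda^* \ge 1$ is found by
bracketed root-finding to $10^{-10}$ in $\lambda$; the reported stress
is $(\lambda^*/2)\hat w'(\lambda^*)$. If the applied pressure exceeds
the first local maximum of $P(\lambda)$ — the limit-point instability
that appears when $\beta$ is small — the model raises an error naming
the limit pressure rather than returning a post-buckling root.

This stand-in exercises the real constitutive law and has the right
qualitative behaviour (stress decreasing in $t$, non-increasing in
$\alpha$ and $\beta$; property-tested on random draws), but it is not a
finite-element solver: per-patient stresses and rupture probabilities
computed with it are not comparable to values obtained from CT-based
geometries, which is why the published per-patient results enter the
package as a bundled printed table rather than as a reproduction
target.

## Kriging surrogate with explicit trend

`kriging_fit()` interpolates $\log\sigma^{\max}_{vm}$ over
$\theta = (t,\alpha,\beta)$ with a squared-exponential kernel and an
explicit trilinear trend
$h(\theta) = (1, t, \alpha, \beta, t\alpha, t\beta, \alpha\beta,
t\alpha\beta)$ under a vague coefficient prior, so any target in the
span of $h$ is reproduced exactly (verified to $10^{-6}$ at random test
points). Numerical choices:

* Inputs are standardized to $[0,1]$ over the training box before the
  kernel and basis are evaluated — $t$ (mm) and $\beta$ (thousands of
  kPa) differ by three orders of magnitude, and an affine change of
  coordinates leaves the trilinear span unchanged.
* The generalized least-squares trend solve is whitened
  ($K = R^\top R$, then QR on $R^{-\top}H$); forming $H K^{-1} H^\top$
  directly squares the condition number and loses six digits on
  trend-dominated data.
* A relative nugget $10^{-10}\zeta_1$ conditions $K$; a prediction
  point that coincides with a training point carries the nugget too,
  so training data are interpolated to machine-level accuracy.
* With exactly as many points as basis functions there are no residual
  degrees of freedom and the likelihood is flat; the fit then keeps its
  heuristic starting hyperparameters and relies on the exact trend.
* Degenerate designs (a coordinate constant across the design) reduce
  the basis to the largest full-rank sub-basis, with a warning.

## Active learning

`train_surrogate_active()` spends forward-model evaluations where they
matter, weighting the surrogate's predictive standard deviation by the
patient's parameter density and the predicted stress level:
$\psi(\Theta) = \delta_{\log\sigma}(\theta)\, p(\log\Theta)\,
\mu_{\log\sigma}(\theta)$. The acquisition grid is a seeded Latin
hypercube of $n_{\mathrm{grid}}$ points over the
$\mu_{\log\Theta} \pm 3\sigma$ box in log space — deliberately uniform,
because $\psi$ already carries the density and a density-distributed
grid would double-count it; a tensor grid at $n_{\mathrm{grid}} = 10^4$
is infeasible in four dimensions. The strength component of each grid
point enters only through the density, mirroring the mixed dependence
of $\psi$. Defaults follow the study settings: $n_{\mathrm{init}} = 8$
initial points (a seeded Latin hypercube of 7 plus the predictive mean
itself), $n_{\mathrm{grid}} = n_{\mathrm{eval}} = 10^4$,
tol $= 10^{-4}$ on the change of the grid average $\hat\psi$.

The loop starts from $\hat\psi_0 = 0$, so at least one acquisition
occurs unless the first $\hat\psi$ is already below tolerance (as for
an exactly trilinear target) or the tolerance is infinite. Negative
predicted log stresses (sub-kPa stresses at box corners) are clamped to
zero inside $\psi$ with a warning. Forward-model failures are logged
and the failing grid point's weight zeroed; more than three consecutive
failures abort. Runs are bit-for-bit reproducible given seed,
configuration and forward model. On the membrane model with a realistic
patient predictive the loop typically stops after 10-20 total
evaluations.

## Risk indices

`prob_rupture_mc()` draws $n_{\mathrm{eval}}$ joint samples of
$\log\Theta$ via the Cholesky factor of $\Sigma_{\log\Theta}$ and
compares the surrogate's mean log stress at each sampled
$(t,\alpha,\beta)$ with the sampled log strength. The inequality is
strict — ties count as non-rupture — and the reported standard error is
$\sqrt{\hat p(1-\hat p)/n_{\mathrm{eval}}}$. Under independence and a
constant stress the estimator reduces to
$\Phi\!\big((\mu_1-\mu_2)/\sqrt{s_1^2+s_2^2}\big)$, which
`prob_rupture_closed_form()` provides as the analytic oracle used in
the tests.

For the RPI, the stress is evaluated at the predictive mean parameters
$\exp(\mu_{\log\theta})$ and divided by the mean strength; by default
the log-normal mean $\exp(\mu_{\log\sigma_\gamma} + \tfrac12
\sigma^2_{\log\sigma_\gamma})$, with a directly supplied physical-space
mean as an alternative (published summary tables report empirical
sample moments, which do not coincide with the log-normal transform of
the rounded log-moments). For the PRRI, the printed definition
evaluates the stress at the *mean* log thickness inside the indicator,
which would make the thickness integration vacuous; the package
evaluates the stress at each sampled thickness (with $\alpha,\beta$
fixed at $\exp$ of their predictive log-means), consistent with the
construction the index originates from, and keeps the literal variant
behind `literal = TRUE` for comparison.

## The synthetic cohort generator

`generate_cohort()` emulates what the framework assumes about the
motivating database: patients contributing 1-4 tissue samples (mean
about 2.2, matching 251 samples from 113 patients), features drawn from
independent Gaussians with the published cohort moments (geometric
features truncated at zero), and log-properties equal to the configured
means plus an optional linear link from standardized features plus
correlated Gaussian noise with the published log-space moments. The
default cross-correlations adopt the published patient-level predictive
correlations ($\rho_{t,\sigma_\gamma} = -0.3214$,
$\rho_{\beta,\sigma_\gamma} = 0.2274$, $\rho_{t,\beta} = -0.1966$,
$\rho_{\alpha,\beta} = 0.1413$) as plausible defaults, since pairwise
cohort correlations are not published; they are fully configurable. The
default link is zero, so the marginal moments are exactly the
configured ones; tests that need feature signal set explicit weights.
Missingness is injected by a separate step with its own rate.

What the generator does *not* emulate: real feature distributions are
skewed and mutually correlated, real missingness is not completely at
random, and there is no imaging or geometry. Passing tests on synthetic
cohorts therefore demonstrate correctness of the machinery and
calibration under the model's own assumptions, not clinical validity.

## Problem sizes and determinism

The test suite and examples run at deliberately small problem sizes:
dense-oracle comparisons on cohorts of up to 10 records,
parameter-recovery and coverage studies at $n = 200$ training records
(100 patients, two samples each, three replicate simulations),
acquisition grids of $10^3$-$10^4$ points, and $10^4$ Monte-Carlo
samples for probabilities. All stochastic entry points take explicit
seeds and restore the caller's RNG state, so every reported number is
reproducible.

## Known limitations

* The membrane balloon is a desk-scale stand-in; absolute stresses and
  rupture probabilities from it are not clinically meaningful and are
  only comparable across patients processed identically.
* Median imputation uses the full surviving dataset once, not per
  cross-validation fold — a small optimistic leakage shared with the
  motivating analysis pipeline, documented rather than hidden.
* The rupture criterion is time-free: it describes risk at the moment
  of data acquisition and says nothing about growth.
* PSMSE conventions differ between groups; the scoring hook is
  pluggable and cross-study score comparisons should not be made
  blindly.
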