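---
title: "Shared-component spatio-temporal disease mapping: model, priors, inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-component spatio-temporal disease mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharedmap)
```

## The model

`sharedmap` fits a joint Bayesian model for a balanced panel of death counts
over areas (countries), years, and disease groups. Counts are Poisson around
expected deaths,

$$Y_{itd} \sim \mathrm{Poisson}(E_{itd}\,\theta_{itd}), \qquad
E_{itd} = P_{it} R_{itd} / 100{,}000,$$

where $P_{it}$ is population exposure and $R_{itd}$ the age-standardized
mortality rate per 100,000, so $\theta_{itd}$ is relative risk against the
age-standardized expectation: $\theta = 1$ means mortality exactly at the
expected level. The log relative risk is a structured additive predictor

$$\log\theta_{itd} = \alpha_d + x_{it}^\top\beta + \lambda_i + u_{id}
 + \phi_t + v_{td} + \psi_{itd}.$$

The scientific point of the decomposition is the *shared* components:
$\lambda_i$ and $\phi_t$ capture spatial and temporal risk variation common
to every disease group (health-system capacity, environment, reporting),
while $u_{id}$ and $v_{td}$ capture disease-specific departures and
$\psi_{itd}$ the residual cell-level interaction. Covariates enter with a
single coefficient vector $\beta$ common to all diseases (the predictor
carries no disease index on $\beta$); a disease-specific-$\beta$ variant
would be a model extension, not a configuration of this package.

Component priors:

* **Spatial (BYM2).** $\lambda$ and each column of $u$ follow the
  reparameterized Besag–York–Mollié prior: a variance-scaled intrinsic CAR
  (precision structure = graph Laplacian $Q = D - W$, scaled so the
  geometric mean of the constrained marginal variances is 1) mixed with an
  iid component, $b = (\sqrt{\rho}\,u^* + \sqrt{1-\rho}\,w)/\sqrt{\tau}$.
  One $(\tau_u, \rho_u)$ pair is shared by all disease-specific spatial
  columns.
* **Temporal (RW1).** $\phi$ and each column of $v$ follow first-order
  random walks, variance-scaled exactly like the BYM2 structured parts so
  that the PC priors on all precisions act on comparable scales.
* **Interaction.** $\psi_{itd}$ iid $N(0, 1/\tau_\psi)$ across all cells,
  grouped by disease with one common precision (the grouped-iid reading of
  the interaction; per-disease precisions would quadruple the
  hyperparameter count for 140 cells each).
* **Intercepts.** $\alpha_d$ iid $N(0, 1/\tau_\alpha)$ — not sum-to-zero
  constrained — with the overall level carried by a global intercept with a
  weak $N(0, 1000)$ prior; fixed effects $\beta$ carry the same weak prior
  (precision 0.001).
* **Hyperpriors.** Every precision gets the penalized-complexity prior
  $p(\tau) = \tfrac{\lambda}{2}\tau^{-3/2}e^{-\lambda\tau^{-1/2}}$,
  i.e. Exponential($\lambda$) on the sd scale with $P(\sigma > U) = \alpha$;
  default $U = 1,\ \alpha = 0.01$. The BYM2 mixing parameters get the PC
  prior built from the Kullback–Leibler distance
  $d(\rho) = \sqrt{2\,\mathrm{KLD}(\rho)}$ to the iid base model, computed
  from the eigenvalues of the scaled structure and calibrated so
  $P(\rho < 0.5) = 2/3$. All eight settings are configurable per component.

### Identifiability constraints

The intrinsic priors are improper; sum-to-zero constraints make the
decomposition identifiable: $\sum_i \lambda_i = 0$ (per connected graph
component), $\sum_i u_{id} = 0$ per disease, $\sum_t \phi_t = 0$, and
$\sum_t v_{td} = 0$ per disease. `build_constraints()` assembles these and
verifies each constraint direction lies in the corresponding null space.

## The adjacency graph

Mortality estimates at national scale over the seven East African Community
states motivate the default graph: queen contiguity on land borders
(BDI–RWA, BDI–COD, BDI–TZA, RWA–COD, RWA–UGA, RWA–TZA, COD–UGA, COD–SSD,
UGA–KEN, UGA–TZA, UGA–SSD, KEN–TZA, KEN–SSD). Whether the lake-separated
COD–TZA pair counts as contiguous is genuinely ambiguous; it is excluded by
default and exposed as `build_eac_graph(lake_edges = TRUE)`. Any other
areal system can be supplied as an edge-list CSV.

## Inference: Metropolis-within-Laplace

The model is a latent Gaussian model: conditional on the eight
hyperparameters $(\tau_\lambda, \tau_u, \tau_\phi, \tau_v, \tau_\psi,
\tau_\alpha, \rho_\lambda, \rho_u)$ the posterior of the latent field is
log-concave (Poisson canonical link + Gaussian priors). Inference proceeds
in two nested layers:

1. **Laplace layer.** `laplace_latent()` finds the joint mode of
   $(\beta, \mu, \alpha, \text{latents})$ by Newton ascent with
   backtracking line search (the objective never decreases; each iteration
   asserts this). The per-row interaction coordinates are eliminated by a
   Schur-complement block solve, so one iteration costs
   $O(n m^2)$ with $m \approx 170$ structured coordinates for the default
   design. The Gaussian approximation at the mode supplies both the
   marginal likelihood (Laplace evidence) and the conditional distribution
   of the latent field.
2. **Hyperparameter layer.** `sample_hyperparameters()` runs adaptive
   random-walk Metropolis on $(\log\tau, \mathrm{logit}\,\rho)$ targeting
   Laplace evidence × PC hyperpriors × Jacobians. The proposal covariance
   is learned from the chain history and the global scale tuned to a 0.35
   acceptance rate during burn-in, then frozen. At every retained iteration
   one latent draw is taken from the conditional Gaussian — this plays the
   role of a full latent refresh and yields joint posterior draws of every
   component, the predictor, and the per-row log-likelihoods reused by the
   diagnostics.

**Parameterization.** Internally the latent field is expressed in
*non-centred spectral coordinates*: each intrinsic component is represented
on the eigenbasis of its scaled structure matrix restricted to the positive
eigenvalues. That basis spans exactly the subspace satisfying the
sum-to-zero constraints, so constraints hold by construction (no projection
or kriging correction inside the optimizer), the prior over coordinates is
proper and diagonal, and the hyperparameters enter only as column scalings
of a fixed design matrix. This is mathematically equivalent to
conditioning-by-kriging on the natural scale — the package also implements
the kriging operator (`krige_constrain()`, `sample_constrained_gaussian()`),
uses it in the simulator, and tests the two routes against each other.

**Numerical choices.** Newton convergence is declared when the gradient
max-norm falls below `1e-8`, the step norm below `1e-10`, or the quadratic
model's predicted gain falls below the floating-point resolution of the
objective (`1e-12 (1 + |f|)`) — at national count scales ($10^4$–$10^5$
deaths per cell) the objective's resolution, not the gradient tolerance, is
binding. A hard guard at $|\eta| > 35$ returns $-\infty$ rather than
overflowing the Poisson mean. Constraint residuals beyond `1e-6` in
natural-scale states are an error, never silently projected away. Posterior
modes in summary tables use a Gaussian-kernel density argmax with Silverman
bandwidth.

## The synthetic-data generator

`simulate_panel()` is the package's test bed and defines its study
conditions: 7 countries × 4 disease groups × 20 years (2000–2019) on the
EAC graph. Its defaults are fixed once and shared by the test suite and
acceptance script:

* populations log-uniform on $10^6$–$10^8$ persons (constant per country
  over the panel — exposure trends are not the object of the test bed);
  baseline disease rates uniform on 20–300 per 100,000: the orders of
  magnitude of national NCD panels, keeping counts informative without
  overflow.
* eight covariates (NDVI, temperature, precipitation, GDP per capita,
  health expenditure, urbanization, population density, PM2.5), each a
  stationary AR(1) in time (coefficient 0.8) around country means smoothed
  once over the graph (weight 0.5) — the simplest mechanism producing the
  temporal and neighbor correlation the model assumes — then shifted to
  plausible natural units.
* true fixed effects of magnitude 0.05–0.20 on the standardized scale,
  matching the effect sizes typical of covariate-adjusted risk models;
  true hyperparameters $\tau_\lambda = \tau_\phi = 10$ (shared-component
  sd ≈ 0.32), $\tau_u = \tau_v = 25$, $\tau_\psi = 100$ (interaction
  sd 0.1), $\tau_\alpha = 4$, $\rho = 0.6$.

What it does *not* emulate: real covariate co-movement (collinearity is
mild by construction, VIF ≈ 1–3, so the VIF screen is exercised but never
triggered), reporting artefacts, population age-structure drift, or
subnational heterogeneity. Passing tests therefore demonstrate correctness
of the machinery and calibration under the model's own assumptions — not
robustness to the misspecification real mortality data would bring.

## Diagnostics

All criteria are computed from the stored draws × rows log-likelihood
matrix: DIC with $p_D$ (mean deviance minus deviance at the posterior mean
predictor), WAIC with $p_\text{WAIC}$ and lppd via log-sum-exp, CPO by the
harmonic-mean identity with failure detection (a row is a failure when one
draw carries > 95% of the harmonic weight or the estimate is non-finite —
counted, never dropped), and the discrete mid-PIT
$P(Y^{rep} < y) + \tfrac12 P(Y^{rep} = y)$ (deterministic, unlike
randomized PIT). LCPO is reported as the *sum* of log-CPO, with the mean
also emitted since conventions differ. Note that in-sample PIT and
predictive coverage are conservative in a model with a per-row interaction
term; the calibration tests instead evaluate PIT uniformity and ≈95%
coverage on fresh replicates drawn from the fitted posterior predictive.

## Design decisions taken where the design was open

* **VIF matrix.** Collinearity is screened on the standardized covariates
  over the unique (country, year) cells — replicating rows per disease
  would only reweight every cell equally — with no extra intercept
  augmentation beyond the regression's own intercept. The raw-scale matrix
  is available through `covariate_cells()` on the unstandardized panel.
* **Z-scoring convention.** Sample sd (denominator $n-1$), recorded in the
  standardization record so coefficients can be mapped back exactly.
* **Canonical row order** is disease-major, then country, then year; every
  latent vector indexes into panel rows through this fixed order.
* **Shared components enter with unit loading** for every disease; no
  disease-specific scaling weights are estimated.
* **Summary mode estimator**: kernel density argmax; degenerate draws
  return the common value.

## Known limitations

* With 7 areas, the shared spatial precision rests on 6 effective
  observations and the intercept precision on 4; their posteriors are
  prior-dominated, and simulation shows their posterior means can sit a
  factor 2–4 from truth. The disease-replicated precisions
  ($\tau_u, \tau_v, \tau_\psi$) are well recovered (within a factor of 2 in
  ≥ 95% of replicate fits), and fixed-effect credible intervals are
  calibrated (≈ 94–95% coverage). This is a property of the study
  dimensions, not of the inference.
* The Laplace layer is a single Gaussian approximation per hyperparameter
  value (no simplified/full Laplace marginal corrections); for Poisson
  counts at the scales simulated, the 1-D quadrature benchmark puts the
  induced bias below 2%.
* Higher-order random walks, Leroux priors, structured (Knorr-Held type
  II–IV) interactions, non-Poisson likelihoods, and estimation of
  shared-component loadings are out of scope.

## Problem sizes used by the test suite

Unit and property tests run on panels from 2×2×2 up to the full 7×4×20
design; calibration properties use 8–50 replicate fits with shortened
adaptive chains (400–700 iterations), which the coverage experiments above
show to be sufficient for interval calibration at these sizes. The analysis
drivers under `analysis/` use a 3,000-iteration chain.
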