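---
title: "Spatial Gaussian copula regression: model, inference, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial Gaussian copula regression: model, inference, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgcreg)
```

## The model

`sgcreg` fits marginal spatial regressions for discrete (and Gaussian)
responses observed either on an areal adjacency graph or at planar
locations. The model couples ordinary GLM marginals through a latent
Gaussian field:

$$
\mathbf{Z} \sim \mathrm{N}(\mathbf{0}, \Omega), \qquad
U_i = \Phi(Z_i), \qquad
Y_i = F_i^{-1}(U_i),
$$

where $\Omega$ is a spatial *correlation* matrix and $F_i$ is the marginal
cdf of $Y_i$ with mean $g^{-1}(\mathbf{x}_i'\beta)$ (plus an optional
offset). By the probability integral transform each $U_i$ is standard
uniform, so each $Y_i$ has exactly its GLM marginal law no matter how
strong the dependence carried by $\Omega$ — the copula injects spatial
structure "from below" rather than through random effects in the linear
predictor. Two consequences drive the design:

* $\beta$ keeps the ordinary population-averaged GLM interpretation, and
* there are no latent effects collinear with the covariates, so the model
  cannot be spatially confounded.

The price is that the joint likelihood for discrete outcomes is an
intractable $2^n$-term sum, which motivates the two-stage procedure below.

### Correlation families

Areal domains (a connected undirected graph $G$ with adjacency $A$ and
degree matrix $D$) use Gaussian Markov random field precisions:

* proper CAR: $Q(\rho) = D - \rho A$, $\rho \in [0, 1)$;
* Leroux: $Q(\lambda) = (1-\lambda) I + \lambda (D - A)$,
  $\lambda \in [0, 1)$, which is exactly the independence model at
  $\lambda = 0$.

The intrinsic limit ($\rho, \lambda = 1$) makes $D - A$ singular and is
rejected. A precision is not an inverse correlation matrix, so it is
rescaled: with $V = \mathrm{diag}(\mathrm{diag}(Q^{-1}))$,
$\Omega^{-1} = V^{1/2} Q V^{1/2}$ has unit-diagonal inverse. The
log-likelihood then expands into sparse pieces
$\tfrac12\log|Q| + \tfrac12\sum_i \log v_i - \tfrac12 w'Qw$ with
$w = V^{1/2} r$, so the dense $\Omega$ is never formed.

Point-level domains use kernels of Euclidean distance: the
effective-range exponential $\exp(-3d/\phi)$ (correlation 0.05 at
$d = \phi$), the powered exponential $\exp\{-(d/\phi)^\nu\}$ with
$\nu \in (0,2]$, and the Matérn
$\tfrac{2^{1-\nu}}{\Gamma(\nu)} (d/\phi)^\nu K_\nu(d/\phi)$. A spherical
taper $\{(1 - d/t)_+\}^2 (1 + d/(2t))$ can be Hadamard-multiplied onto any
kernel matrix to induce sparsity (Schur product theorem keeps it a valid
correlation matrix); entries vanish for $d \ge t$.

### Marginals

Poisson, binomial (success counts out of $N$ trials), Bernoulli, negative
binomial with variance $v(\mu) = \mu + \mu^2/\theta$ (Poisson as
$\theta \to \infty$), and Gaussian, all with canonical links. The negative
binomial dispersion is estimated by alternating IRLS for $\beta$ with
profile ML for $\theta$, matching `MASS::glm.nb` to high accuracy.

## Two-stage inference

1. **Marginal fit.** Fit the ordinary GLM, ignoring dependence. Point
   estimates $\hat\beta$ (and $\hat\theta$) come from this stage alone, so
   they are identical whatever copula is later assumed.
2. **Copula fit.** Standardized residuals
   $r_i = e_i / \sqrt{1 - \hat h_i}$ (Pearson or deviance over the
   leverage correction) are treated as a realization of $\mathbf{Z}$, and
   the dependence parameters maximize
   $\ell(\Omega \mid r) = -\tfrac12 \log|\Omega| - \tfrac12 r'\Omega^{-1}r$.
3. **Parametric bootstrap.** Draw $Z^* \sim \mathrm{N}(0, \hat\Omega)$,
   push through $U^* = \Phi(Z^*)$ and the marginal quantile functions at
   the stage-1 estimates, refit the GLM, and form empirical percentile
   intervals from the $\hat\beta^*$ sample. Positive dependence reduces
   the effective sample size, so these intervals are wider than the Wald
   intervals of stage 1 — that widening is the entire inferential point.

**Residual type.** Deviance residuals are the default stage-2 input; they
are closer to normal than Pearson residuals for the discrete families this
package targets, and in our simulations they recover dependence parameters
with noticeably less attenuation (Pearson remains available via
`residual_type`). Randomized quantile residuals are provided for model
*assessment* only — their randomization deliberately destroys part of the
dependence structure, which is exactly wrong for stage 2.

**Interval flavor.** The bootstrap intervals are empirical percentile
intervals; each level $1-\alpha$ requires $n_b\,\alpha/2 \ge 5$ so that the
interval endpoints are supported by at least a handful of order
statistics. With the default $n_b = 1000$, 99% intervals are well
defined; at the scaled-down $n_b = 200$ used in the fast studies only 95%
intervals are formed.

**Model choice.** `AIC_glm` $= 2p - 2\hat\ell$ (with $p$ counting every
estimated marginal parameter, including $\theta$) selects the response
family; `AIC_cop` $= 2q + \log|\hat\Omega| + r'\hat\Omega^{-1}r$ compares
copulas fitted to the same residual vector.

## Numerical choices

* **Areal likelihood evaluations.** $Q(\rho)$ is an affine family, so one
  symmetric eigendecomposition per graph (of $D^{-1/2} A D^{-1/2}$, or of
  $D - A$ for Leroux) makes $\log|Q|$, the variances
  $\mathrm{diag}(Q^{-1})$, and latent-field sampling $O(n^2)$ for every
  subsequent parameter value. The decomposition is cached on the graph
  object. This spectral route is exact and is tested to $10^{-10}$ against
  the generic path (sparse Cholesky factorization with fill-reducing
  permutation, $\tfrac12\log|Q| = \sum_i \log C_{ii}$, and an exact
  diagonal-of-inverse), which remains the implementation used for one-off
  structures.
* **Kernel evaluations.** Kernels are radial, so they are evaluated once
  per distinct distance and scattered back into the matrix; on regular
  grids this reduces the per-iteration kernel cost by roughly the grid
  size. The Matérn diagonal is set to its limit 1 directly because
  $0 \cdot K_\nu(0)$ is numerically indeterminate, and the scaled Bessel
  function is used to avoid underflow at large $d/\phi$.
* **Optimization.** Dependence parameters are optimized on the logit
  scale and ranges on the log scale. Single-parameter families use
  Brent's method on $[10^{-6}, 1 - 10^{-6}]$ (dependence) or
  $[10^{-3}, 10] \times d_{\max}$ (range). The two-parameter kernels
  (Matérn, powered exponential) have a genuinely multimodal surface with
  a flat near-independence plateau at small $\phi$ or $\nu$: a
  quasi-Newton search started from a single interior point frequently
  terminates on that plateau. The optimizer therefore scans a coarse
  log-grid (7 ranges $\times$ 4 smoothness values) and polishes the best
  point with box-constrained L-BFGS-B, $\nu \in [10^{-4}, 10]$ for the
  Matérn and $(0, 2]$ for the powered exponential. Cholesky failures
  during the search (ill-conditioned kernels at extreme parameters) are
  treated as $-\infty$ likelihood.
* **Bootstrap refits** run through a compiled IRLS (with an alternating
  Newton update for the negative binomial dispersion), validated against
  `glm.fit` and `MASS::glm.nb` at $\sim 10^{-8}$; non-convergent refits
  are dropped and counted, and more than 5% drops is an error rather than
  a silent degradation.
* **Reproducibility.** Every study routine spawns one sub-seed per
  replicate from the root seed, so replicates are individually
  reproducible and results do not depend on batching. Bootstrap draws are
  matrix-sampled once per dataset.

## The scenario simulator

`scenario_config(1..6)` encodes the six study designs used throughout the
package's tests: Poisson/CAR on the $30\times30$ lattice at $\rho = 0.99$
and $0.8$; binomial ($N = 20$)/Leroux on the $40\times40$ lattice at
$\lambda = 0.95$; Bernoulli with the $\phi = 0.3$ effective-range
exponential kernel on a $30\times30$ grid; and negative binomial
($\theta = 3$) with Matérn ($\nu = 1$, $\phi = 0.1$ or $0.03$) on a
$20\times20$ grid. Covariates are always the grid coordinates themselves
(spanning $[-0.5, 0.5]$ in each axis, an east–west and a north–south
effect) with no intercept, with $\beta = (3, 1)$ for the count scenarios
and $(2, 0.5)$ for the binary/binomial ones. The generator draws data by
the exact model chain above, so marginal laws are preserved under
dependence — a property the test suite audits site-by-site with
goodness-of-fit tests.

What the simulator deliberately does *not* emulate: irregular adjacency
graphs (all areal scenarios are rook-adjacency lattices), anisotropy or
nonstationarity, covariates beyond the smooth coordinate surfaces, and
missing data. Passing the simulation studies therefore demonstrates
correctness of the machinery and calibration under the stated designs,
not robustness to those complications. The small-area incidence analysis
in the README (offset Poisson + CAR copula) likewise runs on synthetic
data, since real registry counts of that kind are rarely redistributable.

## Study sizes and what the studies show

The bundled studies (acceptance script and heavy tests) run 200 simulated
datasets per scenario with bootstrap size 200 (1000 for the
strong-dependence CAR scenario, whose 99% intervals need the larger
sample), a deliberate scale-down from 1000×1000 full-size runs; empirical
rates then carry a Monte-Carlo band of about
$3\sqrt{p(1-p)/200}$ — roughly $\pm 8$ percentage points at $p = 0.84$ —
and nuisance medians are compared within the interquartile range of their
sampling distribution. At these sizes the studies reproduce the expected
qualitative pattern sharply: ordinary Wald intervals collapse to far
below nominal coverage under strong dependence while the bootstrap
intervals recover most of it (with 99% intervals needed in the hardest
CAR setting); dependence parameters are recovered with small negative
bias on areal domains; ungrouped binary data yield a severely attenuated
range estimate; CAR and Leroux copulas are nearly indistinguishable by
information criteria while Matérn-vs-powered-exponential discrimination
improves markedly when the latent field is observed directly; and
regression inference is essentially unaffected by fitting the wrong areal
copula family.

## Known limitations

* Joint (one-stage) likelihood or Bayesian estimation is out of scope;
  the two-stage estimates of dependence parameters inherit attenuation
  from treating residuals as the latent field, most visibly for Bernoulli
  responses.
* Kernel matrices without tapering are dense, so point-level fits scale
  as $O(n^3)$ per likelihood evaluation; tapering (or an areal
  formulation) is the intended route for larger $n$.
* Only the spherical taper is provided; smoother Matérn processes would
  ideally use Wendland-family tapers.
* No shapefile/polygon ingestion: areal graphs enter as edge lists or
  adjacency matrices.
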