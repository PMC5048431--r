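---
title: "Three equivalent representations of the Ising model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three equivalent representations of the Ising model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingtriad)
```

## The model and why three stories fit it

For a vector $x \in \{-1,+1\}^N$ of binary variables the Ising model is

$$
p(x) \;=\; \frac{1}{Z}\,
\exp\Big(\sum_i \delta_i x_i + \sum_{i<j} \sigma_{ij}\, x_i x_j\Big),
\qquad
Z = \sum_{x} \exp(\cdot),
$$

with main effects $\delta$ and a symmetric coupling matrix $\Sigma$.  It is
the standard model for pairwise associations among binary variables —
symptoms, items, magnetic moments — and is usually read as a *network*:
variables affect each other directly through the couplings
$\sigma_{ij}$.

The same distribution supports two other causal narratives, and this
package makes those narratives computational objects:

* **Latent variable (common cause).** Because $x_i x_i = 1$, the diagonal
  of $\Sigma$ is arbitrary; shifting it by
  $c = \max(0, -\lambda_{\min}(\Sigma))$ makes the matrix positive
  semi-definite, $\Sigma + cI = Q \Lambda Q^\top$.  Each squared
  eigen-component $\tfrac12 \lambda_r (q_r^\top x)^2$ in the exponent can be
  linearised with the Gaussian identity
  $e^{a^2} = \pi^{-1/2}\!\int e^{-t^2 + 2at}\,dt$ (the
  Hubbard–Stratonovich trick), introducing one latent variable per
  non-zero eigenvalue.  The result is a multidimensional IRT model with
  discrimination matrix $A$: conditional on $\theta \sim$ the latent
  density, items are independent logistic responses, and marginalising
  $\theta$ returns exactly $p(x)$.  With one eigenvalue and equal loadings
  this is the Rasch model.
* **Collider (common effect).** Alternatively, attach to each non-zero
  eigenvalue a binary effect variable with
  $p(e_r = 1 \mid x) = \exp\big(\tfrac12 \lambda_r (q_r^\top x)^2 -
  \log M_r\big)$ and let the causes $x_i$ be *marginally independent* with
  $p(x) \propto \exp(\delta^\top x)$.  Conditioning on all effects being
  present multiplies the independent marginal by the effect probabilities;
  every factor that does not depend on $x$ cancels in the renormalisation
  and the conditional is again exactly $p(x)$.  Associations appear purely
  through endogenous selection bias.

The three parameterisations are therefore statistically indistinguishable;
what differs is the mechanism each one narrates.  The package's job is to
convert between them exactly and to *certify* the equivalence numerically,
in total variation distance over the enumerated configuration table.

## The discrimination scaling

Writing the Gaussian identity with $a_r = \sqrt{\lambda_r/2}\,(q_r^\top x)$
and rescaling the auxiliary variable so its kernel is standard normal
gives $E_{\theta_r \sim N(0,1)}\!\left[e^{\sqrt{\lambda_r}(q_r^\top x)\,
\theta_r}\right] = e^{\lambda_r (q_r^\top x)^2/2}$, i.e. the loading of
item $i$ on dimension $r$ is $\alpha_{ir} = \sqrt{\lambda_r}\, q_{ir}$ and
$A A^\top = \Sigma + cI$.  An alternative convention without the square
root circulates in prose descriptions of this construction, but it fails
dimensional analysis — $A A^\top$ would equal $(\Sigma + cI)$ only after
squaring the eigenvalues — and the distribution-level tests in this package
(quadrature marginal vs. enumerated pmf) single out the $\sqrt{\lambda}$
convention unambiguously.  Under it the latent density is the tilted
Gaussian $f(\theta) \propto e^{-\theta^\top\theta/2} \prod_i 2\cosh(\delta_i
+ a_i^\top \theta)$ and the posterior is the convenient exact Gaussian
$\theta \mid x \sim N(A^\top x, I)$ — the engine of the augmented Gibbs
sampler.

## Numerical choices

* **Spin coding** is $\pm 1$ throughout; 0/1 appears only for effect
  variables.  The exponent counts each unordered pair once; the matrix
  form $\tfrac12 x^\top \Sigma x$ with zero diagonal (used for the
  eigendecomposition) is identical because the half compensates the double
  count.
* **Enumeration cap.** Exact tables materialise $2^N$ rows; the cap is
  $N \le 20$ (about a million configurations) with an explicit error above
  it.  All exactness claims are scoped to this regime; no approximate
  inference is offered beyond it.
* **Canonical configuration order** is lexicographic with $-1$ before
  $+1$, item 1 varying slowest.  Fixing the order makes tables from
  different representations comparable element-wise and CSV exports
  byte-stable.
* **Log-domain arithmetic** everywhere a normalising constant appears
  (log-sum-exp; $\log 2\cosh$ via `abs(x) + log1p(exp(-2 abs(x)))`), so
  exponents up to about 700 in magnitude are safe.
* **Eigenvector sign convention**: the largest-magnitude entry of each
  column is made positive (ties to the lowest index).  Eigenvectors are
  defined only up to sign; fixing it makes every conversion a pure
  function with bitwise-reproducible output.
* **Rank tolerance.** Eigenvalues above $10^{-10} \lambda_{\max}$ count as
  latent dimensions; numerically zero eigenvalues are dropped from $A$ and
  from the effect list, which changes nothing since their factors are
  constants.
* **Quadrature.** The latent marginal uses a Gauss–Hermite tensor grid
  (probabilists' scaling), default order 30 per dimension, capped at 4
  dimensions because the cost is order$^m$; above that the collider route
  gives the same pmf with no integration at all, and the error message
  says so.  In the joint weight the $2\cosh$ normalisers of the
  conditional cancel against the tilt of $f(\theta)$, so the integrand is
  a Gaussian moment-generating function — smooth, and rapidly better
  approximated as the order grows.  The quadrature table is renormalised
  at the end, so residual error sits in the constant, not in probability
  ratios.
* **Collider bound.** $\log M_r = \tfrac12 \lambda_r N$ is sufficient
  because $(q_r^\top x)^2 \le N$ for unit $q_r$.  It is deliberately the
  loosest analytically safe choice: the conditional distribution is
  provably invariant to it (tested), and a simple bound keeps the
  construction transparent.  The price is selection efficiency — the
  forward-then-select sampler's acceptance rate decays like
  $e^{-N \sum_r \lambda_r / 2}$ — so the sampler refuses below an
  acceptance floor of $10^{-6}$ rather than spin forever.
* **Samplers.** Systematic-scan single-site Gibbs (simpler to reproduce
  than random scan, equally correct), burn-in default 1000 sweeps,
  thinning default 1.  All samplers use R's Mersenne-Twister stream, so a
  single `set.seed()` replays any run on any platform.  Monte Carlo
  standard errors for MCMC output use batch means (50 batches) to absorb
  autocorrelation; i.i.d. output uses the naive estimator.

## What the generators emulate

`random_ising(n, density, scale)` draws sparse-to-dense symmetric
couplings and main effects as independent normals — the generic
"arbitrary network" test case.  After the diagonal shift such matrices are
numerically full rank, which is realistic and exercises the collider route
at full dimension, but puts the tensor quadrature out of reach for
$N > 4$.  `random_low_rank_ising(n, rank, scale)` therefore draws a random
loading matrix with rows rescaled to a common length, so the shifted
coupling matrix has *exactly* the requested rank: these models are the
natural battery for the latent route, mirroring how low-dimensional factor
structure is the regime where latent-variable modelling is used in
practice.  Neither generator emulates sampling noise, missingness, or
model misfit in empirical data: a passing battery certifies the
mathematical equivalence of the parameterisations at machine precision,
not that any particular data set is well described by an Ising model.

## Verification scale

The standard batteries use 50 seeded models with $N \in 4\ldots 8$,
coupling scales 0.2 and 0.5, densities 0.3 and 1 (full-rank battery) or
ranks 1–3 (low-rank battery) — sizes at which exact enumeration is
instantaneous and the full 50-model certification completes in seconds.
Sampler concordance is checked at $N = 6$ with $2\times 10^5$ retained
draws per sampler, comparing all 21 first and second moments against
enumeration within four Monte Carlo standard errors.  The order sweep
{10, 20, 30, 40} shows quadrature error falling from roughly $10^{-7}$ to
the double-precision floor; beyond the floor (total variation around
$10^{-14}$) monotonicity is no longer meaningful and only non-increase is
asserted.

## Known limitations

* No estimation of $\delta, \Sigma$ from data — the package manipulates
  and verifies parameterised models, it does not fit them.
* No approximate inference for $N$ beyond the enumeration cap, and no
  sparse-grid or Monte Carlo integration for latent rank above 4 (the
  collider route covers that case exactly).
* The latent density is fixed by the construction; substituting other
  latent distributions breaks the equivalence and is refused rather than
  approximated.
* Partial conditioning (a subset of effects present) is observable through
  `joint_pmf()` but carries no equivalence guarantee; the theorem concerns
  conditioning on *all* effects.
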