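---
title: "Low-complexity GP regression from differential-operator eigenbases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-complexity GP regression from differential-operator eigenbases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcgp)
```

## The model

A Gaussian-process regression model observes $y_i = f(t_i) + \tau_i$ with
$\tau_i \sim N(0, \sigma_N^2)$ and a zero-mean GP prior on $f$. The exact
posterior requires factoring the $N \times N$ Gram matrix
$K + \sigma_N^2 I$, an $O(N^3)$ operation with $O(N^2)$ memory that
becomes impractical for large $N$.

This package replaces $f$ by its truncated Karhunen–Loève expansion
$f_m(t) = \sum_{j=1}^m a_j \phi_j(t)$ with independent coefficients
$a_j \sim N(0, \lambda_j)$, which induces the rank-$m$ Mercer covariance
$k_m(t,s) = \sum_{j=1}^m \lambda_j \phi_j(t)\phi_j(s)$. On $N$ inputs the
Gram matrix factors as $\tilde K = \Phi\Gamma\Phi^\top$ with
$\Phi_{ij} = \phi_j(t_i)$ and $\Gamma = \mathrm{diag}(\lambda_j)$, and the
matrix-inversion lemma turns every $N \times N$ solve into an $m \times m$
one through $M = \Phi^\top\Phi + \sigma_N^2\Gamma^{-1}$:

$$\bar f_\star = \phi_\star^\top M^{-1}\Phi^\top y, \qquad
  v(f_\star) = \sigma_N^2\,\phi_\star^\top M^{-1}\phi_\star,$$

with the log marginal likelihood available in a matching determinant-lemma
form. Fitting costs $O(Nm^2)$, learning $O(m^3)$ per objective
evaluation, and memory $O(m^2)$ because $\Phi$ is streamed in row blocks
and only $\Phi^\top\Phi$, $\Phi^\top y$ and $y^\top y$ are retained.

Rather than computing eigenpairs numerically from an integral operator,
the basis families are closed-form eigenbases of classical differential
operators; the kernel eigenvalues are the reciprocals of the operator
eigenvalues $\gamma_j$, optionally scaled by an amplitude. Six families
are provided (`eigen_basis()`): a Dirichlet sine basis on $[0,1]$ with a
Matérn-type spectrum $\gamma_j = \sigma^{-2}(\epsilon + j^2\pi^2)^\alpha$,
and the Legendre ($j(j+1)$), Laguerre ($j^2$), Hermite ($4j^2$),
Chebyshev ($j^4$) and Jacobi ($j(j+\alpha+\beta+1)$) orthogonal-polynomial
families, each orthonormal under its weight $\rho$ on its natural domain.
For the Laguerre, Hermite and Chebyshev operators the first-order
eigenvalues are negative, so the iterated (squared) operator is used: the
eigenfunctions are unchanged and the eigenvalues squared, which is what
the $j^2$, $4j^2$ and $j^4$ entries above already reflect. The truncation
error is the eigenvalue tail $\xi_m = \sum_{j>m}\lambda_j$
(`basis_mise()`), available in closed or rapidly convergent form per
family.

## Parameters that matter

* `m` — truncation order. Governs rank, cost and truncation error;
  the benchmark protocol uses `m = 25` throughout. Not optimized (it is
  an integer model-size choice); compare fits by `log_marginal()`.
* `sigma2`, `eps`, `alpha` — the sine family's variance, shape and
  (integer) smoothness. $\alpha$ plays the role of $\nu + 1/2$; larger
  values give faster eigenvalue decay, i.e. smoother draws.
* `sigma2` for the polynomial families — a global amplitude multiplying
  all $\lambda_j$ (default on, value 1). The tabulated polynomial spectra
  carry no free scale, and a fixed-scale prior cannot match data of
  arbitrary magnitude; the amplitude factors out of the eigenfunctions so
  no formula changes. `amplitude = FALSE` restores the literal spectrum.
* `noise_var` ($\sigma_N^2$) — observation noise variance, strictly
  positive.
* The Jacobi exponents `alpha_jac`, `beta_jac` (> −1) are held fixed by
  default (defaults −0.5, −0.3).

### Input mapping

Data rarely live on a family's natural domain, so each basis carries an
invertible affine map fitted once from the training inputs
(`fit_input_map()`) and stored with the model:

* compact domains — training range onto the central 96% (a 2% margin per
  side keeps test points slightly beyond the training range valid);
* Laguerre — training range onto $[0, m/2]$. The orthonormal Laguerre
  functions grow like $e^{t/2}$ beyond their oscillatory region, so
  spreading data proportionally to $N$ (e.g. unit spacing) makes
  $\Phi^\top\Phi$ catastrophically ill-conditioned; keeping the data
  within the oscillatory region of all $m$ retained eigenfunctions
  preserves agreement with the exact-GP route at the $10^{-10}$ level;
* Hermite — standardized to zero mean and unit variance;
* a degenerate (single-point) range maps the point to the domain centre.

### Centering

All retained eigenfunctions are orthogonal to the constant mode (excluded
because its operator eigenvalue is zero), so every prior draw — and hence
every posterior mean — integrates to zero against the weight. Responses
with a nonzero level are therefore centred on request
(`center = TRUE` in `lcgp_fit()`, `cgp_fit()`, `lcgp_learn()`; the
training mean is stored and added back to predictions). The pipeline
(`run_fit_predict()`) centres by default; the low-level fitters do not,
preserving the literal algebra.

## Numerical choices

* **Whitened solve.** $\Gamma^{-1}$ overflows when $\lambda_m$ is tiny
  (fast-decaying spectra), so $M$ is factored in the whitened form
  $M' = \Gamma^{1/2}\Phi^\top\Phi\,\Gamma^{1/2} + \sigma_N^2 I$, whose
  condition number is bounded by $(\lambda_1\|\Phi\|^2 +
  \sigma_N^2)/\sigma_N^2$. Predictions and the likelihood are
  algebraically identical; `lcgp_chol()` recovers the factor of the
  unwhitened $M$ exactly as $\Gamma^{-1/2}L'$.
* **Jitter.** If the Cholesky factorization fails, $10^{-10}
  \mathrm{tr}(M')/m$ is added once with a warning; a second failure is a
  hard error reporting $\lambda_1/\lambda_m$. A diagnostic warning is
  also emitted whenever $\lambda_1/\lambda_m > 10^{12}$.
* **Polynomial evaluation** uses three-term recurrences; the Hermite
  recurrence carries its normalization incrementally so $2^j j!$ never
  appears (it would overflow near $j = 25$).
* **Quadrature oracles.** Orthonormality and the integral eigen-relation
  are verified with family-matched Gauss rules
  (`basis_quadrature()`). Gauss–Laguerre and Gauss–Hermite weights span
  hundreds of orders of magnitude and eigenvector-based rules lose the
  tiny ones to rounding, so nodes are Newton-polished and weights
  evaluated from the classical derivative formulas; Gauss–Jacobi uses a
  Golub–Welsch construction.
* **Predictive variance** is computed from triangular solves and is
  nonnegative by construction in the reduced-rank path; the exact path
  clips round-off negatives at zero (warning below $-10^{-8}$).
* **Matérn MISE tail** is summed explicitly for 2000 terms with a
  midpoint-rule integral remainder, accurate to ~$10^{-14}$, so the
  telescoping identity $\xi_m - \xi_{m+1} = \lambda_{m+1}$ holds to
  rounding for every family.

## Hyperparameter learning

`lcgp_learn()` ascends the approximate log marginal likelihood in
log-parameter space, $\theta_j \leftarrow \theta_j + \eta g_j$, with
central finite-difference gradients (step $10^{-4}(1 + |\log\theta_j|)$;
each evaluation rebuilds the $m \times m$ system, so gradients cost
$O(p\,(Nm^2 + m^3))$) and backtracking halving of $\eta$ whenever a step
would decrease the objective — the returned likelihood trace is
non-decreasing by construction. Defaults: $\eta = 0.1$, tolerance
$10^{-5}$ on the gradient norm, at most 500 iterations. Finite
differences were chosen over analytic gradients because they are uniform
across the six families and the objective is cheap; an analytic path
would only change constants.

The tunable set is $(\sigma^2, \epsilon, \sigma_N^2)$ for the sine family
and (amplitude, $\sigma_N^2$) for the polynomial families; $\alpha$ and
$m$ are integers and never optimized. The objective is multimodal in the
kernel parameters, so `inits =` accepts a list of starting points and
returns the best final likelihood; `lcgp_default_inits()` supplies a
deterministic three-point ladder (unit and moment-matched amplitude,
smooth and rough shape). With very fast-decaying spectra
($\alpha \ge 3$) the likelihood surface around generic starts is nearly
flat and the ascent can stall; this is a known limitation — use
multi-start with amplitude-matched values, or fix $\alpha \le 2$.

## What the synthetic generators emulate

`simulate_dataset()` reproduces the benchmark protocol: 140 inputs
uniform on $[0,1]$ (random by default; the protocol's "uniformly
distributed" is ambiguous, and an equispaced design is available by
flag), responses $f(t) + \tau$ with $\tau \sim N(0, 0.1)$ — the 0.1 is a
variance — and a 40/100 train/test split. The two truths are the
Beta(2,5) density $30t(1-t)^4$ and the quasi-periodic $t\sin(10t)$.
`sample_prior()` and `sample_brownian()` draw Karhunen–Loève paths with
$a_j \sim N(0,\lambda_j)$; the Brownian motion and bridge series
($\lambda_j = 4/((2j-1)^2\pi^2)$ and $1/(j^2\pi^2)$, sine eigenfunctions)
provide analytically known covariances, $\min(t,s)$ and $\min(t,s)-ts$,
against which the sampling machinery is validated.

These generators share none of the features that make real data hard —
heteroscedastic or non-Gaussian noise, irregular input densities,
covariate error — so passing tests demonstrate correctness of the
algebra and calibration under the stated model, not robustness beyond
it.

### Metrics and the evaluation convention

`ise()` is the average squared difference between prediction and truth
over the evaluation points (a trapezoid-rule variant is available);
`r_squared()` is the usual $1 - SS_{res}/SS_{tot}$. Test metrics are
computed against the *true* function at the held-out inputs: against the
noisy test responses the attainable $R^2$ is information-bounded near
0.6 for $t\sin(10t)$ (signal variance ≈ 0.13 against noise variance
0.1), which would say more about the noise than about the fit. Because a
single 40-point noisy training draw leaves substantial seed-to-seed
variation in test $R^2$ (roughly 0.6–0.9 for the oscillatory benchmark
even at the likelihood optimum), the package's validation reports the
median over five replicate datasets, a choice mirrored from the
noise-recovery experiment's median-over-seeds design.

Problem sizes used by the validation suite — $N \le 50$, $m = 10$ for the
reduced-rank/exact equivalence sweeps; the full protocol sizes ($N =
140$, $m = 25$) for the benchmark reproduction; $N = 12{,}000$ for the
streaming-memory check; 5000 paths × 200 terms for the Brownian sampler —
were chosen so each check exercises the regime it is about while the
whole suite stays desk-scale.

## Known limitations

* Inputs are scalar; no tensor-product multivariate bases.
* Gaussian likelihoods only.
* Prediction requires inputs inside the affinely mapped natural domain;
  the library errors on violations, while the command-line pipeline
  clamps offending points to the domain edge with a warning.
* The exact-GP path is capped at $N = 2000$ by default (override with
  `force = TRUE`) because its cost is cubic.
* The Laguerre family is numerically delicate and, consistent with its
  weaker predictive behaviour, not part of the headline benchmark pair.
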