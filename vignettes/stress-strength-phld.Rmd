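---
title: "Stress–strength reliability under the Poisson half-logistic distribution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-strength reliability under the Poisson half-logistic distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model behind `phldss`, the numerical
decisions baked into it, and what the test suite does and does not
establish about behaviour on real data.

## The model

A component of strength $X$ subjected to a stress $Y$ survives exactly when
$Y < X$; the stress–strength reliability is $R = P(Y < X)$.  `phldss`
models both variables as independent Poisson half-logistic (PHLD)
random variables.  The PHLD compounds a half-logistic baseline with a
zero-truncated Poisson frailty: with scale $\alpha > 0$, shape
$\lambda > 0$ and the half-logistic kernel
$\Delta(x) = \tanh(\alpha x / 2)$,

$$F(x) = \frac{e^{\lambda \Delta(x)} - 1}{e^{\lambda} - 1}, \qquad
  f(x) = \frac{2\alpha\lambda\, e^{-\alpha x + \lambda \Delta(x)}}
              {(e^{\lambda} - 1)(1 + e^{-\alpha x})^2}, \qquad x \ge 0.$$

As $\lambda \to 0$ the PHLD reduces to the half-logistic distribution with
scale $\alpha$; $\lambda$ tilts mass towards larger values.  The quantile
function is closed form,
$x_p = \tfrac{2}{\alpha}\operatorname{atanh}(\xi)$ with
$\xi = \log\{p(e^\lambda - 1) + 1\}/\lambda$, which both `rphld` and the
synthetic-data generator invert (inverse-transform sampling — the only
random-generation route in the package, so a seed determines a sample
exactly).

For $X \sim \mathrm{PHLD}(\alpha_1, \lambda_1)$ and
$Y \sim \mathrm{PHLD}(\alpha_2, \lambda_2)$,

$$R = \int_0^\infty f_1(x)\, F_2(x)\, dx,$$

which has no closed form in general.  When $\alpha_1 = \alpha_2$ the
substitution $t = \Delta(x)$ collapses the integral and $R$ depends on the
shapes only:
$$R = \frac{\lambda_1 (e^{\lambda_1+\lambda_2} - 1)}
           {(\lambda_1+\lambda_2)(e^{\lambda_1}-1)(e^{\lambda_2}-1)}
      - \frac{1}{e^{\lambda_2}-1}.$$
This closed form is used internally as an independent check of the
common-scale series evaluation.

## Quadrature is authoritative; series are cross-checks

`reliability_quadrature` evaluates $R$ twice — once on the half-line
through $f_1 F_2$, once on the unit interval after substituting
$t = e^{-\alpha_1 x}$ — and insists the two agree to $10^{-8}$.  Every
downstream consumer (the maximum-likelihood plug-in, the delta-method
gradient, the Monte Carlo harness) uses quadrature values.  On the unit
interval the stress factor is kept as the ratio
$\operatorname{expm1}(\lambda_2 \Delta)/\operatorname{expm1}(\lambda_2)$;
written as a difference of two terms of size $1/(e^{\lambda_2}-1)$ it loses
catastrophic amounts of precision once a fitted shape is near zero.

The series representations of $R$ expand the exponential factors of the
integrand (indices with factorial decay) and the binomial kernels.  The
binomial expansions are used at the boundary of their disc of convergence:
their partial sums oscillate without damping rather than converge.  The
common-scale series makes this explicit — its inner alternating sum has
terms of constant magnitude $1/(i+1)$ — and is Abel summable only.  The
package therefore evaluates every such index with a convergence-accelerated
alternating-series scheme (the Cohen–Villegas–Zagier algorithm, `n = 40`
terms by default), which returns the Abel value with geometric accuracy,
and evaluates the $(2-v)^{-(i+2)}$ kernel through its absolutely convergent
expansion about $v = 0$ (geometric ratio $1/2$) — the Abel value of the
boundary expansion.  With these choices the general-case series agrees with
quadrature to about $10^{-6}$ over the tabulated parameter range, and the
common-scale series to $10^{-10}$.

The same treatment applies to the auxiliary integrals behind the expected
information and the gradient of $R$ (`nabla_integral`, `zeta_integral`,
`zeta_star_integral`).  One genuine numerical limit is worth recording: the
two-marginal $\zeta$ series at shape values around 4 cannot do better than
roughly $10^{-5}$ *relative* accuracy in double precision.  Its
coefficient sequences grow like $e^{c\sqrt{m}}$, so the accelerated sums
cancel ~10 significant digits; taking more acceleration terms makes the
rounding blow-up worse, not better.  Forty terms is near the optimum, and
the tests assert relative agreement at $10^{-5}$.  Quadrature, which is
what the package actually uses, is unaffected.

## Maximum likelihood

The general four-parameter log-likelihood separates into an
$(\alpha_1, \lambda_1)$ block depending only on the strength sample and an
$(\alpha_2, \lambda_2)$ block depending only on the stress sample, so
`fit_general` solves two independent two-parameter problems.  Each is
maximized by L-BFGS-B on **log-parameters** (positivity without constraint
handling) with the analytic score mapped through the chain rule, started
from $\alpha_0 = \log(3)/\mathrm{median}$ (the shape-free half-logistic
median relation) and $\lambda_0 = 1$, with a $3\times3$ log-grid
multi-start as fallback.  `fit_common` maximizes the three-parameter
shared-scale likelihood jointly; being nested, its optimum can never exceed
the general model's.

Convergence is declared on the **projected gradient in the log
parameterization**.  This matters for a reason users of small samples will
meet quickly: when a sample looks plain half-logistic, the shape's MLE sits
at the $\lambda \to 0$ boundary.  The log-scale gradient vanishes there
while the original-scale score does not; such fits are reported as
converged boundary solutions (the box is $|\log\theta| \le 30$).  In
simulation cells with $\lambda \approx 1$ and $n = 20$–$40$ this affects a
noticeable fraction of replicates, and their delta-method intervals can be
extremely wide — the information matrix is near-singular at the boundary,
in which case a pseudo-inverse is used and a warning raised.

## Interval estimates

* **Asymptotic (delta method).**  $\widehat{\mathrm{Var}}(\hat R) =
  B^T I^{-1} B$ with $B$ the gradient of $R$ at $\hat\theta$ and $I$ an
  information matrix.  The *observed* (numeric negative Hessian of the
  log-likelihood) information is the default for real-data intervals; the
  *expected* information is assembled from the auxiliary integrals and
  validated against Monte Carlo curvature averages in the tests.  The
  numeric gradient (central differences of the quadrature $R$, step
  $\epsilon^{1/3}\max(|\theta|,1)$ capped at $\theta/2$ so boundary fits
  stay feasible) is authoritative; the integral-based analytic gradient
  must agree with it to $10^{-4}$ or `grad_R` errors.  Interval endpoints
  are clipped to $[0,1]$ and clipping is flagged.
* **Bootstrap.**  Nonparametric: both samples are resampled independently
  with replacement at their original sizes and the model refitted from the
  original MLE.  The percentile interval takes draw $\lceil B\epsilon/2
  \rceil$ from the bottom and from the top of the sorted replicates
  (type-1 empirical quantiles); the studentized interval uses the
  symmetric form $\hat R \pm |t^*_{(\epsilon/2)}|\,\mathrm{se}(\hat R^*)$,
  with an asymmetric two-tailed variant behind a flag.  Refit failures are
  counted, and more than 1% of them is an error rather than a silent drop.
  A parametric-resampling switch exists but is off by default.
* **HPD.**  The Chen–Shao construction: the narrowest window of
  $\lceil (1-\epsilon) N \rceil$ consecutive order statistics of the
  posterior draws of $R$.  Ties are broken by the first minimal window.

## Bayesian estimation

All parameters get independent Gamma(shape, rate) priors; the default
Gamma(0.001, 0.001) is near-flat on the positive half-line and fully
configurable.  Sampling is componentwise random-walk Metropolis within
Gibbs with normal proposals; non-positive proposals are rejected through a
$-\infty$ target, which preserves the standard ratio because the proposal
is symmetric.  Proposal scales adapt during burn-in towards a 25–45%
acceptance rate (stochastic-approximation updates of the log standard
deviation every 50 sweeps) and are then frozen, so the kept chain is
Markov.  Burn-in defaults to 10% of the run.  Each kept draw's reliability
uses a fixed 201-node Gauss–Legendre rule on the probability transform
$R = \int_0^1 F_2(Q_1(p))\,dp$ — a bounded smooth integrand, accurate to
$10^{-9}$ over the exercised parameter ranges and, unlike adaptive
quadrature, constant-cost per draw.

Point estimates follow the loss functions: posterior mean (SEL), median
(AEL), LINEX $-\tfrac1c \log E[e^{-cR}]$, general entropy
$(E[R^{-q}])^{-1/q}$, and MAP.  Two choices deserve a note.  First, the
LINEX estimator is implemented with $e^{-cR}$ inside the expectation; the
variant with $e^{+cR}$ produces negative "estimates" of a probability and
violates the ordering LINEX $\le$ SEL for $c > 0$ that the implemented form
satisfies by Jensen's inequality.  Second, MAP is computed as the mode of a
Gaussian-kernel density estimate (Silverman bandwidth) of the $R$ draws,
because the posterior of $R$ is only available through draws; a plug-in
variant at the joint parameter posterior mode is deliberately not the
default, since the mode of a nonlinear function's distribution is not the
function of the mode.  Default loss parameters are $c = 2$ and $q = 3$.

## The Monte Carlo harness and the synthetic generator

`run_sim_cell` draws both samples by inverse transform, refits, and
aggregates bias, MSE, average interval length and empirical coverage.
Replicate $r$ of a cell runs on a sub-seed derived deterministically from
the cell seed, so cells are reproducible as a whole and replicate-level
results can be regenerated in isolation.  Replicates whose fit fails are
excluded and counted, with a 2% ceiling before the cell errors; at the
smallest cells (n = 20 with shapes near 1) about 1% of replicates sit too
close to the parameter boundary to process and this is reported, not
hidden.

The generator draws exactly from the model.  That is the point — the
harness measures estimator behaviour *under the model* — and also the
limitation: passing cells say nothing about misspecification, censoring,
dependence between stress and strength, or measurement rounding, all of
which real data (including the bundled waiting times, recorded to 0.1
minutes) exhibit.  The goodness-of-fit layer (`ks_statistic`) is the only
guard in that direction, and its p-value is the plain asymptotic one-sample
Kolmogorov value with no correction for estimated parameters, so it is
optimistic when used after fitting — adequate for descriptive use, not a
calibrated test.

Problem sizes in the shipped tests are the package's own choice of a
thorough-but-quick regime: simulation cells of 200–1000 replicates,
bootstrap sizes of 300–1000, chains of $10^3$–$10^4$ iterations, and
coverage checks at 300 replicates × 300 resamples.  The full
tables-scale study (every cell × 1000 replicates × 1000 resamples ×
Bayes-within-replicate) is available through `summarize_grid` with the
corresponding settings and runs for hours rather than minutes.

## Known limitations

* Complete samples only; no censoring or record-value variants.
* The expected-information route relies on numerically delicate auxiliary
  integrals at large shapes; observed information is the recommended (and
  default) source for real-data intervals.
* The $\zeta$-series cross-check saturates at ~$10^{-5}$ relative accuracy
  (see above); this bounds the series *validation* precision, not the
  precision of any reported estimate.
* The KS p-value ignores parameter estimation (see above).
* MCMC adaptation targets a fixed acceptance band; heavily multimodal
  posteriors (not observed for this model) would need a different sampler.
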