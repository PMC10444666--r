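---
title: "Marginal maximum likelihood for hierarchical MPT models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal maximum likelihood for hierarchical MPT models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A multinomial processing tree (MPT) model explains the category
frequencies of a product-multinomial experiment through latent
cognitive-process probabilities $\theta_1, \dots, \theta_S$ arranged on
the branches of processing trees.  Each category system (tree) $k$
contributes a multinomial block; the probability of a branch is a
product $\prod_s \theta_s^{a}(1-\theta_s)^{b}$ with non-negative
integer exponents, and a category's probability is the sum over the
branches terminating in it.  The running example throughout the package
is the pair-clustering model of free recall: parameters $c$ (cluster
storage), $r$ (cluster retrieval), $u$ (storage–retrieval of a
non-clustered pair word), and $a$ (singleton storage–retrieval), with a
four-category tree for word pairs and a two-category tree for
singletons.

The hierarchical ("latent-trait") extension lets $R \le S$ of the
process parameters vary across the $T$ participants: on a link scale
(probit by default, logit optional),
$$\theta_{st} = g^{-1}(b_{st}), \qquad
  \mathbf b_t \sim \mathrm{MVN}(\boldsymbol\mu_t, \boldsymbol\Sigma),
  \qquad \boldsymbol\mu_t = \boldsymbol\mu + \boldsymbol\Gamma \mathbf X_t,$$
while the remaining $S - R$ parameters are fixed effects
$\theta_{st} = g^{-1}(\beta_s + \boldsymbol\gamma_s \mathbf X_t)$.  The
mean structure is identified by fixing the intercepts of random
parameters to zero.  The package estimates
$(\boldsymbol\beta, \boldsymbol\gamma, \boldsymbol\mu,
\boldsymbol\Gamma, \boldsymbol\Sigma)$ by maximizing the marginal
log-likelihood
$$\ell = \sum_{t=1}^{T} \log \int
  f(\mathbf n_t \mid \mathbf b_t)\,
  \phi(\mathbf b_t; \boldsymbol\mu_t, \boldsymbol\Sigma)\,
  d\mathbf b_t ,$$
with the per-person integrals approximated numerically.

## Integral approximations

All three back ends share the per-person mode
$\hat{\mathbf b}_t$ (maximizer of the joint log-density) and curvature
$\hat{\boldsymbol\Omega}_t$ (inverse negative Hessian at the mode):

* **Laplace**: the integrand is replaced by its Gaussian approximation,
  giving $(2\pi)^{R/2}|\hat{\boldsymbol\Omega}_t|^{1/2}
  f(\mathbf n_t \mid \hat{\mathbf b}_t)\,\phi(\hat{\mathbf b}_t)$.
  It is fast but known to degrade when few responses per person make
  the integrand non-Gaussian; the simulation harness reproduces its
  high failure rate at 25 responses per person.
* **Adaptive Gauss–Hermite quadrature (AGHQ)**: a tensor-product rule
  with $M$ nodes per dimension ($M^R$ node vectors per person),
  recentred and rescaled by $\hat{\mathbf b}_t$ and the Cholesky factor
  of $\hat{\boldsymbol\Omega}_t$.  AGHQ with one node per dimension is
  exactly the Laplace approximation, which the tests assert to machine
  precision.  A budget guard refuses $M^R > 10^6$ node vectors and
  points the user to QMC.
* **Quasi Monte Carlo (QMC)**: $M$ Halton points (radical-inverse
  sequence, $r$-th prime base in dimension $r$, zero point skipped)
  mapped through the normal quantile and affinely transformed per
  person by the mode and curvature.  Because the transformed points
  follow the proposal $\mathrm N(\hat{\mathbf b}_t,
  \hat{\boldsymbol\Omega}_t)$ rather than the random-effect
  distribution, the integrand is importance-weighted by the ratio of
  the two densities; without that correction the estimator would target
  the wrong measure.  Halton sequences are deterministic, so the whole
  estimation path is reproducible without a seed.

Accuracy is certified in the test suite against brute-force oracles: a
Simpson-rule oracle in one dimension (AGHQ within $10^{-8}$, QMC with
4096 points within $10^{-3}$) and a dense trapezoid grid in two
dimensions (both within $10^{-3}$ of the total log-likelihood).

## Modes, curvature, and numerical choices

Per-person modes are found by damped Newton iterations, vectorized
across persons, to a gradient-norm tolerance of $10^{-8}$ (at most 100
iterations; persons that fail are flagged and the fit carries a
warning).  The Newton steps and the curvature matrices use the **exact
analytic Hessian** of the joint log-density in $\mathbf b$: writing
$u_s = a_s/\theta_s - b_s/(1-\theta_s)$ per branch, the second
derivatives of the conditional log-likelihood follow from the
branch-product structure, and the chain rule through the link adds the
second link derivative on the diagonal.  An independent
finite-difference Hessian is kept in the package purely as a
cross-check (the tests require agreement to $10^{-6}$); the analytic
version was chosen because it is deterministic, exact at clamped
probabilities, and several times faster, which matters because the
curvature is refreshed at every outer objective evaluation.

Inverse-link values are clamped to $[10^{-12}, 1 - 10^{-12}]$ so the
conditional log-likelihood stays finite for extreme random-effect
draws; all likelihood accumulation is in log space (log-sum-exp over
nodes), and branch probabilities are evaluated from logarithms so deep
trees cannot underflow.

## Estimation

The covariance matrix is parameterized by its log-Cholesky factors
(logarithms on the diagonal), so any unconstrained real vector decodes
to a positive-definite $\boldsymbol\Sigma$; the analytic score of
$\boldsymbol\Sigma$ is propagated through the factorization by the
chain rule.  Starting values are the link-transformed fixed-effects fit
of the pooled (aggregate) frequencies with
$\boldsymbol\Sigma_0 = 0.3\,\mathbf I$ — aggregate fits are cheap and
stable, and the moderate starting variance avoids starting on the flat
part of the variance profile.

The outer maximization is a PORT quasi-Newton run (`stats::nlminb`)
over the flat free-parameter vector, using the analytic marginal
gradient (the quadrature-weighted posterior expectation of the joint
score, evaluated with the same nodes as the likelihood).  The
per-person modes are refreshed — warm-started from the previous point —
at every objective evaluation, so the surface being maximized is the
adaptive approximation itself.  Two numerical facts shaped this design:

* The quadrature approximation of the marginal gradient is the exact
  gradient of the *frozen-mode* objective but only an approximation of
  the gradient of the mode-adaptive objective.  At coarse node counts
  the discrepancy is of the order of the integration error, so any
  line-search optimizer stalls once parameter moves fall below that
  scale.  The residual gradient at the reported optimum therefore
  reflects integration accuracy, not optimizer slack; the convergence
  diagnostic scales it per recorded response.
* A pure two-step alternation (full inner maximization with frozen
  modes, then a mode refresh, repeated) can overshoot in the covariance
  direction and then crawl back at a contraction rate near 0.85, or
  terminate at visibly worse points.  The package therefore finishes
  with an *accept-only* polish: a few damped frozen-mode inner solves,
  each kept only if it improves the refreshed marginal log-likelihood,
  with the first rejected or negligible cycle certifying stationarity.

A fit is reported as converged only if the optimizer terminated
regularly, all estimates are finite, $\boldsymbol\Sigma$ is positive
definite, and every standard error is defined and positive — the same
admissibility definition the simulation harness uses for its
convergence rates.

Standard errors come from the observed information: by default central
finite differences of the analytic marginal gradient (modes refreshed
at each perturbed point), optionally the "exact" assembly from
quadrature-approximated inner integrals of the score and its
derivative; the two agree to within 2% on the test problems.
Confidence intervals are formed on the estimation scale: link scale for
means, intercepts and covariate weights, and the natural covariance
scale for the entries of $\boldsymbol\Sigma$ via the delta method from
the log-Cholesky block.  The reporting scale for interval coverage is a
genuinely open choice with no single community convention; the
delta-method variance scale was chosen because variances and
covariances are what practitioners read off the fitted object.

## Model comparison and random-effect prediction

Nested fits are compared by the likelihood-ratio statistic
$LR = -2(\ell_r - \ell_u)$ against a central $\chi^2$ with the
free-parameter-count difference as degrees of freedom (nestedness is
the caller's responsibility).  AIC and BIC use
$df = R + (S-R) + p_{\Gamma} + p_{\gamma} + R(R+1)/2$ and, for BIC,
$n$ equal to the total number of recorded responses — the natural
scalar reduction of the per-person frequency vectors.  Multinomial
coefficients are included in all log-likelihoods so that AIC/BIC are
comparable across software; they cancel in gradients and LR tests.

Random effects are predicted either by the per-person modes (already
available from estimation) or by the empirical-Bayes posterior mean
$\mathrm E[\mathbf b_t \mid \mathbf n_t]$, approximated with the fit's
own quadrature rule and validated against a dense-grid oracle in the
test suite.  Persons with no recorded responses get their prior mean under both
estimators, and the empirical-Bayes predictions exhibit the expected
shrinkage toward $\boldsymbol\mu_t$.

## The synthetic-data generator and the simulation harness

`default_population()` encodes the reference simulation population:
pair-clustering, probability-scale means
$(0.50, 0.40, 0.25, 0.15)$ for $(c, r, u, a)$, link-scale covariance
$$\boldsymbol\Sigma = \begin{pmatrix}
 0.50 & 0.08 & 0.04 & 0.00\\
 0.08 & 0.35 & 0.03 & 0.00\\
 0.04 & 0.03 & 0.20 & 0.07\\
 0.00 & 0.00 & 0.07 & 0.20\end{pmatrix},$$
and a roughly 80/20 split of each person's responses between the pair
and singleton systems (20/5, 60/15, or 100/25 per person).  Three
interpretation choices are deliberate and documented rather than
inherited: the means are read on the probability scale and transformed
by the forward link (variances like 0.50 are impossible for
probabilities with these means, and a link-scale mean of zero would
make relative bias undefined); $\boldsymbol\Sigma$ is link-scale; and
the generating link defaults to probit, the latent-trait convention,
with logit available as an option.

The generator draws $\mathbf b_t$ from the multivariate normal, maps
to process probabilities, and draws each tree's counts from a
multinomial — person-level frequencies, not trial-level responses,
matching the sufficiency of the frequency representation.  It emulates
between-person heterogeneity and multinomial sampling noise only: real
data also carry item effects, serial-position effects, and possibly
non-normal or mixture-distributed person effects, so passing tests
certify the estimator under the stated model, not robustness to those
violations.

`run_study()` wraps the full bias/coverage/convergence experiment over
a $T \times N \times$ method grid.  Relative bias
($100(\bar{\hat\vartheta} - \vartheta)/\vartheta$) compares means on
the probability scale and (co)variances on the link scale; parameters
with zero truth are excluded.  Coverage counts Wald intervals
(estimate $\pm 1.96\,$SE, on the link scale for means and the natural
scale for covariance entries).  Non-converged replications are excluded
from bias and coverage but counted in the convergence rate, mirroring
how such studies report the two separately.  Per-replication
group-averaged quantities carry Monte Carlo standard errors so that
comparisons against large-replication reference values remain
well-defined at reduced scale.

## Problem sizes used by the shipped experiments

The package's own acceptance experiments run at reduced scale, chosen
as the smallest designs whose Monte Carlo error bands still make the
comparisons informative: 50 replications of the AGHQ 3-node cell at
$T = 75$, $N = 125$ (bias and coverage), 25 replications of the AGHQ
4-node cell at the same design point (coverage of the variance group),
and 10 replications of a large recovery cell at $T = 300$, $N = 125$
with 4 nodes per dimension.  The reference values for these cells come
from 500-replication experiments, so all comparisons are made through
the Monte Carlo bands described above.  All seeds are fixed in the
test code.

## Known limitations

* Tensor-product AGHQ is exponential in $R$; beyond roughly six random
  parameters QMC is the only practical back end here (no sparse grids,
  Monte Carlo EM, or variational approximations).
* The likelihood-ratio test does not verify structural nesting of two
  EQN models plus restrictions; it checks only the degrees-of-freedom
  difference and the ordering of the log-likelihoods.
* Random effects are participant-level only — no crossed
  participant-by-item structure — and their distribution is assumed
  multivariate normal.
* At 25 responses per person the Laplace back end frequently yields
  inadmissible solutions (undefined standard errors); this is a
  property of the approximation, reproduced rather than repaired here.
  AGHQ with four or more nodes per dimension is the recommended
  default.
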