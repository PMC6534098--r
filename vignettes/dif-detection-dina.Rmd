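---
title: "DIF detection in the DINA model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DIF detection in the DINA model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinadif)
```

## The model

The DINA ("deterministic input, noisy AND") model is a cognitive
diagnosis model for dichotomous test data.  Each of $N$ examinees holds
a binary mastery pattern $\alpha = (\alpha_1, \ldots, \alpha_K)$ over
$K$ attributes, giving $L = 2^K$ latent classes.  A $J \times K$
Q-matrix declares which attributes each item requires.  The latent
response is the conjunction
$\gamma_{nj} = \prod_k \alpha_{nk}^{q_{jk}}$: an examinee either
masters *all* required attributes of item $j$ or counts as a
non-master.  Observed responses are the noisy version,

$$P(x_{nj} = 1 \mid \alpha_n) = g_j^{\,1-\gamma_{nj}} (1 - s_j)^{\gamma_{nj}},$$

with a guessing parameter $g_j$ (non-masters succeeding) and a slipping
parameter $s_j$ (masters failing).  Class membership follows a
saturated log-linear model $p_l \propto \exp(\eta_l)$ with $\eta_L = 0$
for identification; we enumerate classes in binary order with attribute
1 as the most significant bit, so the reference class is full mastery.
The enumeration order is a pure convention — every quantity the package
reports is invariant to it.

`dina()` maximises the marginal likelihood
$\sum_l p_l \prod_j P_{lj}^{x_{nj}} (1-P_{lj})^{1-x_{nj}}$ by EM.  All
likelihood work runs in log space with a per-examinee log-sum-exp, so
$J = 30$ response patterns never underflow.

### Numerical choices in the EM

* **Initialisation**: $g_j = s_j = 0.2$, uniform classes ($\eta = 0$) —
  a neutral interior start.
* **M-step clipping**: updated $g_j$, $s_j$ are clipped to
  $[10^{-4}, 1 - 10^{-4}]$ so every information matrix stays finite.
  No monotonicity constraint ($g_j < 1 - s_j$) is imposed.
* **Convergence** is declared when the maximum absolute change over
  guess, slip *and the class probabilities* drops below `tol`
  (default $10^{-4}$; at most 1000 iterations).  The structural change
  is deliberately measured on the probability scale: the MLE regularly
  places small latent classes on the boundary $p_l \to 0$, where
  $\eta_l \to -\infty$ along a likelihood-flat direction.  A criterion
  on $\eta$ itself would never trigger for such fits even though every
  estimate of interest is stationary, and would misreport a large share
  of well-behaved fits as non-converged.
* **Boundary classes** (estimated probability below $10^{-6}$) are
  excluded from covariance estimation via `free_params()`: a boundary
  parameter has no interior MLE and its score column is numerically
  null, which would make the full information matrix singular.  The
  item-parameter blocks used by the DIF tests are unaffected.

## Covariance estimators

Writing $\beta = (g_1, s_1, \ldots, g_J, s_J, \eta_1, \ldots,
\eta_{L-1})$, the package offers four estimators of
$\mathrm{Cov}(\hat\beta)$:

* **XPD** — inverse of the cross-product of per-examinee analytic
  scores, $\left(\sum_n s_n s_n'\right)^{-1}$;
* **Obs** — inverse of the observed information $-\partial^2 \ell /
  \partial\beta\,\partial\beta'$, computed by central finite
  differences of the analytic score with step
  $10^{-5}\max(1, |\beta_p|)$ and symmetrised;
* **sandwich** — $I_{Obs}^{-1} I_{XPD} I_{Obs}^{-1}$, which collapses
  to the other two when the information equality holds;
* **item-wise** — per item, the inverse of the $2\times 2$ score
  cross-product for $(g_j, s_j)$ only, with posterior weights held
  fixed.  This classical shortcut ignores the structural parameters and
  all cross-item blocks and therefore *underestimates* sampling
  variance — the known source of the inflated Type I error of the
  $W_d$ test that motivates the full-information alternatives.

The scores are exact (they are validated against finite differences of
an independently coded likelihood in the test suite); only the Hessian
is differenced, which keeps every model-specific derivation analytic
while avoiding a closed-form second derivative.  Inversions use a
symmetric solve guarded by a reciprocal-condition-number threshold of
$10^{-12}$; anything below it raises a classed singular-information
error, which the Monte Carlo harness treats as a failed replication.

## The six DIF tests

An item functions differentially when examinees with the same mastery
pattern but from different groups have different success
probabilities: $\Delta_{g_j} = g_{Fj} - g_{Rj} \ne 0$ and/or
$\Delta_{s_j} = s_{Rj} - s_{Fj} \ne 0$ (F = focal, R = reference).
Equal signs give uniform DIF, anything else non-uniform.

The four Wald variants ($W_d$, $W_{XPD}$, $W_{Obs}$, $W_{Sw}$) fit the
model separately per group — with every parameter group-specific the
two-group likelihood factorises, so the joint covariance is
block-diagonal — and test $H_0\!: C v_j = 0$ with
$v_j = (g_{Fj}, s_{Fj}, g_{Rj}, s_{Rj})$,
$C = \begin{pmatrix} 1 & 0 & -1 & 0 \\ 0 & 1 & 0 & -1 \end{pmatrix}$,
$W = (Cv)'(C\Sigma_j C')^{-1}(Cv) \sim \chi^2_2$, where $\Sigma_j$
comes from the respective covariance estimator.

Two matching-variable methods need no model fit:

* **Mantel-Haenszel** stratifies on the observed total score
  $m = 1, \ldots, J-1$ (extreme scores carry no association
  information), drops strata with a zero margin, and uses the
  continuity-corrected $\chi^2_1$ statistic.  The corrected numerator
  is applied exactly as printed — no flooring at zero — so a perfectly
  null table yields $0.25/\sum_m \mathrm{Var}(A_m)$, a documented quirk
  of the formula.  The matching score includes the studied item (thin
  matching, the standard convention).
* **Logistic regression** fits
  $\mathrm{logit}(\pi_n) = \tau_0 + \tau_1 M_n + \tau_2 G_n + \tau_3 M_n G_n$
  and reports the 2-df likelihood-ratio test of
  $\tau_2 = \tau_3 = 0$.  A single joint test is used because it
  covers uniform ($\tau_2$) and non-uniform ($\tau_3$) DIF with one
  decision per item, matching how the Wald tests are scored; the
  separate 1-df sub-tests remain available from the returned
  coefficients.

No anchor purification or multiple-testing correction is applied; each
item is tested at $\alpha = 0.05$.

## What the simulator emulates

`dif_condition()` + `sim_dif_data()` reproduce a standard two-group DIF
study design:

* $J = 30$, $K = 5$, $N = 1000$ split 500/500 (the design fixes only
  the total; an equal split is the neutral choice).  The balanced
  Q-matrix (`sim_qmatrix()`) measures every attribute with exactly 12
  items and mixes 1-, 2- and 3-attribute items.
* Attributes come from a one-factor multivariate probit: $K$ standard
  normals with exchangeable correlation $\rho \in \{0, 0.5, 0.8\}$
  thresholded at zero, giving marginal mastery 0.5 and pairwise
  tetrachoric correlation $\rho$.  Both groups share this process —
  no impact (group ability difference) is simulated.
* Reference item quality is a common value $s = g \in
  \{0.1, 0.2, 0.3\}$ (high/medium/low).  DIF of size 0.05 or 0.1 is
  injected through the sign patterns of $(\Delta_g, \Delta_s)$: two
  uniform patterns and six non-uniform ones.  Low quality (0.1)
  excludes size 0.1, which would push a focal parameter to the
  boundary of $(0,1)$.
* DIF items are 10% ({1, 11, 21}) or 30%
  ({1, 4, 8, 11, 14, 18, 21, 24, 28}) of the test, spread across item
  complexities; the placement is a package convention, as only the
  percentage is part of the design.
* The full factorial with the quality restriction yields the 240
  conditions of `dif_condition_grid()`.

What it does **not** emulate: unequal group sizes, impact, hierarchical
or non-exchangeable attribute structures, Q-matrix misspecification,
polytomous data, or missingness.  Passing Monte Carlo checks therefore
speak to the estimators' behaviour under a correctly specified DINA
model, not to robustness against those violations.

## The Monte Carlo harness

`run_replication()` simulates a data set, fits both groups and applies
every requested method; a replication counts as converged only when
both EM fits converge and every (item, method) decision is testable,
so all methods are compared on identical data.  `run_study()` draws
replications — each from a counter-based child seed of the master
seed, so replacing a failed draw never perturbs the others — until the
requested number of converged ones is reached, and aborts with
diagnostics if more than 20% of draws fail.  Type I error is the flag
proportion over (non-DIF item, replication) pairs, power over (DIF
item, replication) pairs, and empirical Type I error in
$[0.025, 0.075]$ counts as accurate (Bradley's liberal criterion for
nominal 0.05).

### Problem sizes used by the shipped checks

The package's own benchmark runs are desk-scale by design: the power
benchmark (medium quality, $\rho = 0.5$, 10% uniform DIF of size 0.1)
uses 50 converged replications and the size benchmark (medium quality,
$\rho = 0$, size 0.05) 100 replications; unit and property tests use
instances from $N = 4$ oracle checks up to single $N = 2000$ recovery
fits.  The full 240-condition grid with 200 replications per cell is
available by feeding `dif_condition_grid()` and `n_reps = 200` to
`run_study()`.

## Known limitations

* The observed information is a differenced score, not a closed form;
  its accuracy is bounded by the step choice (validated to $10^{-3}$
  relative against an independent double-difference oracle in the
  tests).
* With $N = 500$ per group and 32 latent classes, boundary classes are
  common; their structural variances are deliberately not reported (see
  above).  Consumers who need a full structural covariance should fit
  larger samples or a restricted structural model.
* Separate-group estimation doubles the parameter count; anchoring
  strategies (shared structural parameters, purified matching) are out
  of scope.
* `lr_test()` relies on `stats::glm`; complete separation in tiny
  strata surfaces as a classed untestable-item error rather than a
  silent estimate.
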