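---
title: "Methods: variable selection for high-dimensional censored survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variable selection for high-dimensional censored survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Gene-expression survival studies routinely observe tens of thousands of
features on a few hundred subjects. In that $P \gg N$ regime the unpenalized
Cox proportional hazards estimator does not exist, and practical analyses
combine the Cox partial likelihood with a variable-selection device. This
package implements and compares three such devices on a common footing:

* **CoxLasso** — the $\ell_1$-penalized partial likelihood with
  cross-validated penalty;
* **CoxSis** — marginal sure independence screening (rank covariates by the
  absolute coefficient of their one-covariate Cox fit, keep the top $d$),
  followed by the lasso within the survivors;
* **CoxSisLasso** — a lasso-conditioned screen: the lasso provides a prior
  set $C_0$; every remaining covariate $m \notin C_0$ is then refit jointly
  with $C_0$ and retained in the augmentation $C_1$ when the Wald p-value of
  $\hat\beta_m$ falls below a threshold $\gamma$; a final lasso over
  $C_0 \cup C_1$ picks the reported selection.

The point of the third strategy is the known blind spot of marginal
screening: a covariate can be jointly predictive of survival while its
*marginal* association is nulled by correlation with other active
covariates. Conditioning on a reasonable prior set restores its visibility.

# Model and estimation

The hazard for subject $i$ is $h_i(t) = h_0(t)\exp(x_i^T\beta)$. All
estimation is driven by the log partial likelihood

$$\ell(\beta) = \sum_{k \in D}\Big[x_k^T\beta -
  \log \sum_{j \in R_k} \exp(x_j^T\beta)\Big],$$

with $D$ the event index set and $R_k$ the risk set at the $k$-th event
time. The baseline hazard $h_0$ cancels and is never estimated.

Numerical choices, fixed for reproducibility:

* **Ties.** Breslow's convention throughout (tied event times share one
  risk set, each event contributes its own term). This matches the
  convention of the penalized solver, so strategy refits are consistent
  with the path they came from. Efron weighting is out of scope.
* **Optimizer.** Newton–Raphson from $\beta = 0$ with step-halving;
  convergence when the gradient max-norm drops below $10^{-8}$ or the
  relative log-likelihood change below $10^{-10}$; at most 100 iterations.
  Standard errors come from the inverse observed information at the
  maximum. A monotone (separating) likelihood is reported as
  `converged = FALSE` rather than an error; exact collinearity is an error
  naming the offending features.
* **Stability.** Risk-set sums are computed on times sorted in decreasing
  order with a single cumulative pass, after subtracting the running
  maximum of the linear predictor from the exponent, so the partial
  likelihood cannot overflow. The observed information is assembled from
  two BLAS cross-products (one weighted by the reverse-cumulated inverse
  risk-set sums), keeping genome-scale screening loops fast without
  compiled code.

# The penalized path

The CoxLasso objective adds $\lambda \sum_j |\beta_j|$ to the negative
partial likelihood. Conventions:

* Covariates are standardized internally (mean zero, population variance
  one) before penalization and coefficients are reported back on the
  original scale — the de facto convention of penalized Cox software.
* The grid is log-spaced over 100 penalties from $\lambda_{\max} =
  \max_j |g_j(0)|/n$ (the KKT boundary of the all-zero solution, computed
  from the package's own gradient) down to $0.01\,\lambda_{\max}$ when
  $p > n$, $10^{-4}\lambda_{\max}$ otherwise.
* The convex solver is glmnet's cyclic coordinate descent with warm
  starts. The package treats the solver as a black box and audits it:
  `lasso_kkt()` recomputes the exact partial-likelihood gradient at every
  returned solution and reports the worst violation of the stationarity
  conditions ($|g_j/n| \le \lambda$ on the inactive set,
  $g_j/n = \lambda\,\mathrm{sign}(\beta_j)$ on the active set). Path fits
  use a coordinate-descent tolerance of $10^{-12}$, which keeps KKT
  residuals well below $10^{-5}$.
* Cross-validation uses seeded folds stratified by event status (so no
  fold is event-free), the Verweij–van Houwelingen partial-likelihood
  deviance, and the `lambda.min` rule; the one-standard-error rule is
  available behind a flag but is not the default, since the minimum-rule
  selections are the ones comparable in size to typical reported gene
  signatures. CV fits use a relaxed coordinate-descent tolerance of
  $10^{-6}$: the selected penalty is stable far above that precision, and
  selection needs penalty-level, not coefficient-level, accuracy.

# Screening

* **Marginal screen.** One-covariate Newton fits for all $p$ features,
  ranked by $|\hat\beta_m|$; ties broken by original feature order so the
  top-$d$ sets are nested in $d$. The default budget is
  $d = \lfloor n/\log n\rfloor$, the customary choice in the screening
  literature; it is configuration, not dogma.
* **Conditional screen.** For $m \notin C_0$ the model on
  $C_0 \cup \{m\}$ is refit *jointly* — the $C_0$ coefficients are not
  frozen — warm-started from the $C_0$-only fit. The retention rule is the
  Wald p-value $p_m < \gamma$ with $\gamma = 1/p$ by default ($p$ = total
  covariate count); an alternative magnitude rule $|\hat\beta_m| \ge
  \gamma$ is available as a documented mode, but the p-value rule is
  primary. Candidates whose conditional fit is singular or non-convergent
  are excluded and logged rather than failing a genome-scale screen.
* An empty lasso prior set would leave the conditional screen undefined;
  in that case the marginal screen at the default budget stands in as the
  conditioning set, with a prominent warning.

# Evaluation

* **Concordance.** Harrell's C over permissible pairs: a pair is
  permissible when its follow-up times differ and the earlier time is an
  event; tied scores earn half credit. Pairs with exactly tied times are
  not comparable and are skipped.
* **Generalized $R^2$.** The Cox–Snell form
  $1 - \exp\{-\tfrac2n(\ell(\hat\beta)-\ell(0))\}$, the statistic printed
  by standard Cox summaries.
* **Time-dependent ROC/AUC.** Cumulative cases ($\delta(t) = 1$: event by
  $t$), dynamic controls (event-free at $t$). The population definitions do
  not prescribe an estimator under censoring; the default `km_cd`
  estimator weights observed cases by the inverse Kaplan–Meier censoring
  survival $1/\hat G(T_i^-)$, while the `naive` estimator drops subjects
  censored before $t$ and is exactly testable against a brute-force
  pairwise count. With no censoring the two coincide. The AUC is the
  trapezoid under the empirical ROC polyline with cutoffs at the unique
  scores plus $\pm\infty$, which awards ties half credit. Evaluation times
  inherit the unit of the input times; the CLI default of 30 is
  unit-dependent.
* **Splits.** `train_test_split()` draws uniformly without replacement,
  requires at least two events on each side (redrawing up to 20 times),
  and takes the test set as the complement of the training draw.

# Enrichment

Over-representation of a selection against a GMT collection uses the
hypergeometric upper tail $P(X \ge k)$ — pmf evaluated in log-space —
with Benjamini–Hochberg adjustment by default (Bonferroni available). The
default universe is the feature space the selection was made from, i.e.
the features surviving the variance filter; using the unfiltered array
would overstate significance for sets of highly variable genes.

# The simulator

`simulate_dataset()` draws Gaussian covariates (independent, AR(1), or
equicorrelated, by exact recursions rather than a $p \times p$ factor),
event times by inverse transform from the Cox model with an exponential or
Weibull baseline, and independent uniform $U(0, c^*)$ censoring with $c^*$
calibrated by bisection to a target censoring fraction. Defaults used by
the scenario constructors: unit-rate exponential baseline, 25% censoring —
a typical clinical-cohort attrition level.

Two named scenarios define the package's study conditions:

* `strong_signal_config()`: five actives of magnitude 1 with alternating
  signs, spread evenly across the feature range so the AR(1) correlation
  ($\rho = 0.5$) does not couple them. Every strategy should recover this
  support; it is the benign baseline.
* `hidden_variable_config()`: equicorrelated design with actives
  $\{1,2,3,4\}$ and effects $(\beta_0, \beta_0, \beta_0, -3\rho\beta_0)$,
  so that $\mathrm{Cov}(X_4, X^T\beta) = \beta_4 + 3\rho\beta_0 = 0$.
  Covariate 4 is jointly active but marginally invisible — the
  construction is exact at the covariance level, while the marginal Cox
  coefficient is only approximately zero (the marginal slope is not a pure
  covariance), which the test margins account for. Note the side effect
  that makes the scenario sharp: the *inactive* covariates inherit a
  nonzero marginal association through their correlation with the visible
  actives, so the hidden covariate ranks near the bottom of the marginal
  ordering, not merely below the top.

What the simulator does *not* emulate: microarray noise models (probe
effects, background, batch structure), non-proportional hazards, or
informative censoring. Passing tests therefore demonstrate correctness of
the algorithms under the stated generative model, not robustness to
violations of the Cox assumptions in real cohorts.

# Problem sizes and reproducibility

The simulation studies in the test suite use $n = 300$, $p = 500$, 50
replicates for the support-recovery and hidden-covariate experiments (the
acceptance script reports the same quantities at 12 replicates per study);
oracle checks run at small $n$ where brute-force enumeration is exact.
These sizes give stable pass/fail margins for the rates being tested while
keeping a full run in the minutes range. Every random draw — simulation,
fold assignment, splits — flows from explicit integer seeds, and package
functions restore the caller's RNG state, so identical configurations are
byte-reproducible (the CLI's outputs deliberately contain no timestamps).

# Known limitations

* Breslow-only tie handling; heavy ties shift coefficients relative to
  Efron-weighted software.
* The conditional screen refits $|C_0|+1$ coefficients per candidate; with
  very large prior sets ($|C_0|$ approaching the event count) it becomes
  unstable and the identifiability guard refuses to run.
* The hidden-covariate construction targets one hidden variable; designs
  with several mutually hiding actives are harder and not covered by the
  shipped scenarios.
* The `km_cd` ROC estimator assumes censoring independent of both the
  score and survival; under score-dependent censoring an
  inverse-probability-of-censoring model would be needed.
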