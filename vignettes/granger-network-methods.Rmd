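---
title: "Methods: Granger-causality network inference for microbial time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Granger-causality network inference for microbial time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grangernet)
```

## The model

`grangernet` treats a community time series as a collection of
univariate series $x_i(t)$, $t = 1..T$, one per OTU or environmental
factor, sampled on a common (typically monthly) grid. The working model
for any ordered pair is a lag-$p$ linear autoregression. The restricted
model predicts the target from its own past,

$$x_2(t) = \sum_{k=1}^{p} a_2(k)\, x_2(t-k) + u_2(t),$$

and the full model adds the candidate cause's past,

$$x_2(t) = \sum_{k=1}^{p} a_{2,2}(k)\, x_2(t-k)
         + \sum_{k=1}^{p} a_{2,1}(k)\, x_1(t-k) + w_2(t).$$

Granger causality of $X_1$ on $X_2$ is the log ratio of the residual
variances, $\mathrm{GC} = \ln(\hat\sigma^2_u / \hat\sigma^2_w)$. Both
models are fit by OLS on the identical window $t = p+1..T$, so with the
maximum-likelihood variance estimator $\hat\sigma^2 = \mathrm{RSS}/(T-p)$
the normalisations cancel and the statistic reduces to
$\ln(\mathrm{RSS}_r/\mathrm{RSS}_f)$. Nesting guarantees it is
non-negative up to floating-point noise.

Assumptions worth keeping in mind: linear dynamics, Gaussian-ish
residuals, *stationarity* of every series entering the scan, and a
sampling interval short enough that causal influence is visible at lag
$\ge 1$. Causality here is predictive (the source's past improves
prediction of the target), not interventional.

### Significance

The no-causality null (all cross-lag coefficients zero) uses
$$F = \frac{T - 2p - 1}{p}\cdot
      \frac{\mathrm{RSS}_r - \mathrm{RSS}_f}{\mathrm{RSS}_f}
  \sim F(p,\; T - 2p - 1).$$
We keep this df convention literally, with $T$ the full series length,
even though the fitted window has $T-p$ observations and the full model
(with intercept) leaves $T-3p-1$ residual df. The two conventions differ
by a factor $(T-2p-1)/(T-3p-1)$ that is negligible at the package's
target lengths, and the literal form preserves the exact identity
$\mathrm{GC} = \ln(1 + F\,p/(T-2p-1))$, which the test suite asserts to
1e-10 on every scanned pair as an internal consistency check. The
calibration consequence is measured, not assumed: on 2000 simulated
independent AR(1) pairs at $T = 44$, $p = 1$, the rejection rate at
$\alpha = 0.05$ must land in $[0.03, 0.07]$ and the p-value distribution
within KS distance 0.05 of uniform.

An intercept is always included by default (abundances are not
mean-zero); `intercept = FALSE` restores the textbook equations exactly.

### Lag order

Field datasets rarely justify large $p$: with monthly sampling and
$T \approx 44$–72, each extra lag costs two to three coefficients per
equation. The default is BIC selection over $1..p_\max$ with
$p_\max = \min(4, \lfloor T/10\rfloor)$, scored for the two-equation
bivariate system on the common window $t = p_\max+1..T$; ties break to
the smaller order, and `globalP = TRUE` forces the minimum over per-pair
selections onto every pair for comparability. Candidate orders whose
design is collinear (deterministic series) are treated as infeasible
rather than as errors.

## Multiple testing

A scan is one family of $n(n-1)$ ordered-pair tests — OTU–OTU, OTU–env,
env–OTU and env–env together, since a single q-threshold governs the
whole graph. Storey's q-value procedure estimates the null proportion
$\pi_0$ by smoothing $\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$
over $\lambda = 0.05, 0.10, \dots, 0.95$ with a df-3 smoothing spline and
evaluating at $\lambda = 0.95$; then
$q_{(i)} = \min_{j\ge i} \pi_0\, m\, p_{(j)}/j$. A non-positive $\pi_0$
estimate (dense signal, or a tiny family) is clamped to $1/m$ with a
warning. With `pi0Method = "bh"` the arithmetic is arranged to reproduce
`p.adjust(..., "BH")` bit for bit, which doubles as a cross-method check:
edge selection at $q < 0.05$ must then coincide with BH selection. The
smoother needs a family of at least a few dozen p-values to be
meaningful; for the 2- and 6-test families that arise in motif-scale
simulations the package's own tests use the BH mode, and we recommend
the same to users scanning fewer than ~20 variables.

Degenerate pairs — a perfect full-model fit, e.g. a deterministic target
— are reported with status `"degenerate"` and excluded from the FDR
family rather than being assigned $p = 0$.

## Conditional causality and pruning

With three or more interacting factors a bivariate scan cannot tell a
direct edge from a mediated one: in a chain $Y \to Z \to X$ the pair
test will often flag $Y \to X$. For an edge under scrutiny the
conditional models add the mediator's lags to both sides:

$$X_t = \sum_k A_{xx,k}X_{t-k} + \sum_k A_{xy,k}Y_{t-k}
      + \sum_k A_{xz,k}Z_{t-k} + \varepsilon_{x,t},$$

against the reduced model without the $Y$ block, giving
$\mathrm{GC}_{Y\to X\mid Z} = \ln(\operatorname{var}\varepsilon' /
\operatorname{var}\varepsilon)$. With an empty conditioning set this
reduces to the bivariate statistic exactly (asserted to 1e-12), a
useful regression guard.

Design choices that were genuinely open:

* **Mediator enumeration.** Candidates for edge $i \to j$ default to
  vertices $z$ with both $i \to z$ and $z \to j$ in the *unpruned* graph
  — the only configuration in which a two-step path can explain the
  direct edge. A wider policy (`mediators = "all"`) conditions on every
  other variable, but at $T \approx 44$ conditioning on ~90 variables
  jointly is hopeless, so mediators are always tested one at a time in
  the trivariate model.
* **Decision rule.** The default is an F-test on the conditional model
  at $\alpha = 0.05$, with $df_2 = (T-p) - (\text{full-model
  coefficients})$: an edge stays only if it survives *every* mediator
  ("any spurious mediator removes it"). A raw threshold on the
  conditional statistic (`rule = "gc_threshold"`) is provided for
  replication of threshold-style analyses, but a fixed cutoff on a
  variance ratio has no calibrated error rate, so it is not the default.
* **Single pass.** All pruning decisions are made against the original
  edge set; pruning is therefore order-independent and idempotent
  (re-pruning a pruned graph changes nothing, which the tests assert).
  Conditional tests are confirmatory and are not re-entered into the FDR
  family.
* **Cycles.** Mutual causality and longer cycles are legitimate outputs
  of the procedure; they are kept and announced (a warning lists
  non-trivial strongly connected components) rather than forbidden.

## Preprocessing

* **Missing data** are deleted listwise: any time point with a missing
  value in any variable is dropped for all variables, because every
  regression needs aligned lags on one shared grid. Fewer than `minT`
  (default 10) surviving points is an error. Missingness is `NA`-coded
  on input; an observed zero is never treated as missing.
* **Abundance filter.** OTUs with mean $< 1$ *and* zeros in more than
  half the time points are removed (dropout guard). The conjunction is
  grammatically ambiguous in common usage, so the combiner is
  configurable (`combine = "or"`); "and" — remove only when both
  conditions hold — is the default. Environmental variables are exempt:
  the criterion is defined for count-like taxa.
* **Stationarity screen.** Every variable is tested with the augmented
  Dickey–Fuller regression (constant, no trend — seasonal or trending
  variables are removed, not detrended), augmentation order chosen by
  AIC over $0..\lfloor (T-1)^{1/3}\rfloor$, MacKinnon response-surface
  p-values, $\alpha = 0.05$. Variables failing to reject the unit root
  are removed; constant series are removed with a warning. The
  implementation is validated against an independent `lm()` fit of the
  auxiliary regression, and its size/power are measured in the test
  suite (random-walk pass rate in $[0.03, 0.07]$; AR(0.3) at $T=500$
  retained $>95\%$).

## The simulator

`simulateVAR()` draws from a stationary VAR($p$) with a user-specified
coefficient array ($b_{j\to i,k}$ = effect of $j$'s lag $k$ on $i$),
Gaussian innovations, a 200-step burn-in, and an explicit mandatory seed
(global RNG state is saved and restored). `makeMotif()` provides the
null/pair/chain/fork/collider structures with cross-coefficient 0.6 and
self-coefficient 0.3 — a persistent but clearly stationary regime in
which a pair edge at $T = 300$ is essentially always detectable, chosen
once as the benchmark condition. Optional transforms shift series
non-negative or Poisson-round them to mimic count data; optional
missingness exercises the deletion path.

What the simulator does *not* emulate: compositional closure (relative
abundances summing to one), seasonality, regime shifts, measurement
error correlated across taxa, and nonlinear dynamics. Passing the
simulated benchmarks therefore demonstrates correctness of the
*procedure* under its own model, not robustness of Granger inference on
any particular real dataset.

## Numerical conventions

* Nested RSS differences are clamped at zero before the F statistic;
  tiny negative GC values (−1e-16-ish) are reported as computed.
* Writers order edges lexicographically by source then target and print
  doubles with 17 significant digits, so outputs are deterministic and
  diffable; GraphML round-trips statistics within 1e-12.
* Rank-deficient designs name the collinear columns in the error; a
  duplicated mediator is refused rather than silently dropped.

## Problem sizes used in the test suite

Statistical properties are verified at sizes chosen to make the checks
sharp yet quick on a laptop: oracle equivalence on 50 random pairs at
$T=60$; null calibration on 2000 pairs at $T=44$; mediation behaviour on
500 chain replicates at $T=300$ (spurious-edge removal $\ge 80\%$ among
bivariate-significant replicates, true-edge retention $\ge 95\%$);
ADF size on 2000 random walks at $T=200$; determinism on a 20-variable
network (380 ordered-pair tests). `scripts/acceptance.R` recomputes a
summary of these operating characteristics from a single command-line
seed.

## Limitations

Granger causality is predictive, pairwise-linear and sampling-rate
bound: influences faster than the sampling interval, purely
contemporaneous dependence, and latent confounders outside the measured
set are all invisible or misattributed. Estimates at $T \lesssim 50$
have substantial variance, and the conditional screen only protects
against mediators that were themselves measured and detected. Treat
edges as hypotheses for experimental validation, not as established
mechanism.
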