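---
title: "Constrained Bayesian relative-risk regression: models, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained Bayesian relative-risk regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbayes)
```

## Why a constrained sampler

For common binary outcomes the odds ratio is a poor stand-in for the
relative risk or prevalence ratio, and the model that estimates the
RR/PR directly — the binomial GLM with log link — is only defined on the
coefficient region where every fitted probability is at most one:

$$\theta_i = \exp(\mathbf{x}_i'\boldsymbol\beta) \le 1 \quad \forall i.$$

Frequentist maximum likelihood often runs into this boundary and fails
to converge. The Bayesian treatment is conceptually simple: the
restriction truncates the posterior support, and any sampler that
rejects proposals outside the region targets the correct truncated
posterior. This package implements that treatment for three models:

* **Log-binomial** (independent binary data): $\theta_i$ as above;
  $\exp(\beta_k)$ is the RR (or PR) of predictor $k$.
* **Mixed-effects log-binomial** (clustered binary data):
  $\theta_{ij} = \exp(\mathbf{x}_{ij}'\boldsymbol\beta + u_i)$ with a
  normal random intercept $u_i \sim N(0, \sigma_u^2)$ per cluster.
* **Log-multinomial** (independent polytomous data): for non-reference
  categories $j = 1, \dots, J-1$,
  $\theta_{ij} = \exp(\mathbf{x}_i' \mathbf{B}_j)$, with the reference
  probability the complement $1 - \sum_j \theta_{ij}$, which must stay
  non-negative. Coefficients for the reference category are redundant
  and not estimated.

### The constraint, precisely

`constraint_ok()` uses the *non-strict* inequality $\theta_i \le 1$: the
boundary itself is admissible, and the likelihood alone handles the
degenerate case ($\theta_i = 1$ paired with an observed $y_i = 0$ is a
log-zero term, so the log-likelihood is $-\infty$ there). For the
multinomial complement the same convention applies (complement $\ge 0$,
with $-\infty$ likelihood whenever an observed category has probability
zero); the choice between strict and non-strict is immaterial for the
sampler because boundary states have likelihood zero exactly when they
conflict with the data.

For the mixed model, the restriction is enforced **at the currently
sampled cluster effects for the observed clusters**. A for-all-$u$
restriction is impossible with unbounded normal effects: whatever the
coefficients, some $u$ exists that pushes a probability past one. The
practical consequence is that the fitted model guarantees valid
probabilities for the observed clusters at every retained draw, but the
implied population model remains a normal-effect approximation near the
boundary. The synthetic-data generator faces the same tension and
resolves it by rejection (below).

## Priors

Coefficients — every entry of $\boldsymbol\beta$ or $\mathbf{B}$ — get
independent $N(0, 10^6)$ priors; the random-effect standard deviation
gets a uniform prior on $[0.01, 100]$. Both are deliberately vague so
the data dominate; the same normal prior is applied to each multinomial
row. All four numbers are configurable through `prior_spec()`. Note the
uniform lower bound keeps $\sigma_u$ away from zero, so posteriors for
near-independent clustered data pile up against $\sigma_u = 0.01$
(visible as an ICC mode around $10^{-4}$).

## The sampler

The engine is component-wise random-walk Metropolis over all scalar
parameters: each coefficient, each cluster effect $u_i$, and
$\sigma_u$. Design points:

* **Constraint as truncation.** Proposals violating the constraint (or
  leaving the prior support) get posterior density zero and are
  rejected. This is equivalent to sampling the truncated posterior and
  preserves reversibility; no clipping or projection is performed.
* **$\sigma_u$ on the log scale**, with the Jacobian correction
  $\log\sigma' - \log\sigma$ added to the acceptance ratio; proposals
  outside $[0.01, 100]$ are rejected via the prior support.
* **Adaptation only during burn-in.** Per-parameter proposal scales
  follow Robbins–Monro updates
  $\log s \mathrel{+}= t^{-0.6}(\alpha_t - \alpha^\*)$ toward a target
  acceptance rate $\alpha^\* = 0.30$, and are frozen at the end of
  burn-in, so the retained part of each chain is a fixed-kernel Markov
  chain and draws need no reweighting.
* **Incremental linear predictors.** A coefficient move shifts
  $\boldsymbol\eta$ by a column multiple; a $u_i$ move touches one
  cluster's rows; a $\sigma_u$ move touches no likelihood term. The
  cached state is refreshed from scratch every 1000 sweeps to keep
  floating-point drift at machine-epsilon scale, and a test asserts the
  cache agrees with fresh density evaluation at the end of every run.
* **Initialization.** Coefficients start at the robust-Poisson fit;
  if that start violates the constraint the intercept is shifted down by
  $\max_i \eta_i + \delta$ (default $\delta = 0.01$), placing the
  largest fitted probability at $e^{-\delta}$. Cluster effects start at
  0, $\sigma_u$ at 0.5; chains beyond the first jitter the coefficients
  slightly (SD 0.02) to overdisperse the starts, re-applying the shift
  so starts are always valid. For multinomial models each category row
  starts at the Poisson fit of its indicator outcome, with all
  intercepts shifted together until the complement is positive.
* **Convergence.** `gelman_rubin()` is the classic potential scale
  reduction factor $\sqrt{((n-1)/n\,W + B/n)/W}$ — no chain splitting or
  rank-normalization — computed per parameter on every run;
  `summarize_chains()` warns above 1.1. `ess()`/`mcse()` provide
  autocorrelation-aware Monte-Carlo errors.
* **Seeds.** `chain_settings(seed=)` drives everything: chain sub-seeds
  are drawn once from the master seed, so runs are reproducible
  draw-for-draw.

Default settings (3 chains, burn-in 50,000, another 50,000 sweeps
thinned by 100) mirror the smallest production-scale run the models were
originally reported with; tests and the acceptance script use much
smaller documented settings, since the properties they check are
statistical rather than draw-for-draw. `chain_settings()` enforces at
least 1000 retained draws *in total across chains* — the estimation
minimum — which the production default meets with 1500.

## Estimators

* **Point estimate: posterior mode.** The argmax of a Gaussian KDE
  (Silverman's rule-of-thumb bandwidth) on a 512-point grid spanning the
  sample range, so boundary-adjacent modes are representable. Below 30
  draws the median is returned with a warning. Grid size and bandwidth
  rule are arguments of `posterior_mode()`.
* **Interval: equal-tail credible interval**, i.e. empirical quantiles
  at $(1-\gamma)/2$ and $1-(1-\gamma)/2$ with linear interpolation
  between order statistics (the type-7 convention — stated because tail
  quantiles at a few thousand draws are convention-sensitive).
* **Ratio scale from transformed draws.** RR/PR summaries exponentiate
  the draws first, then take mode and quantiles. For quantiles this
  coincides with exponentiating the coefficient-scale interval (exactly
  so when the quantile index $(n-1)p$ is integral, and up to
  interpolation between adjacent order statistics otherwise); for the
  KDE mode it does not — the mode is not equivariant under nonlinear
  transforms, and the ratio-scale mode is systematically below
  $\exp(\text{coefficient mode})$ for right-skewed draws. This is why
  tabulated ratio modes cannot be recovered by exponentiating tabulated
  coefficient modes.
* **ICC.** For the mixed model the draw-wise transform
  $\sigma_u^2/(\sigma_u^2+1)$ of the variance draws gives a full
  posterior for the ICC (mode + equal-tail interval). The formula comes
  from the latent-variable view of the log link: the residual of the
  latent continuous variable is unit-mean exponential, variance 1,
  replacing the logistic $\pi^2/3$ of `icc_logistic()`. Both formulas
  are strictly increasing in $\sigma_u^2$ and bounded in $[0,1)$, with
  the log-binomial form always the larger.

## Frequentist comparators

* `fit_poisson_robust()`: `stats::glm` Poisson IRLS with the HC0
  sandwich (`sandwich::vcovHC`). HC0 — no small-sample correction — is
  the documented flavour; on any 2×2 table the slope is exactly the
  crude log-RR and the robust SE equals the delta-method closed form.
  Wald intervals use the normal quantile (1.959964 at 95%).
* `fit_logbinomial_mle()`: Fisher scoring (expected-information weights
  $\theta/(1-\theta)$) with step-halving whenever a step would leave
  $\{\max_i \eta_i \le 0\}$ or decrease the likelihood. A
  boundary-pinned optimum or iteration cap sets `converged = FALSE`
  while still reporting coefficients — non-convergence is a *state*, not
  an exception, because that is exactly the phenomenon of interest; the
  fitted probabilities never exceed 1.
* `fit_gee()`: exchangeable-correlation GEE written in-package (no GEE
  package is assumed): moment estimator of $\alpha$ from Pearson
  residuals, closed-form exchangeable inverse in the weighted scoring
  step, cluster-robust sandwich covariance. $\alpha$ is reported as the
  GEE ICC estimate, truncated into $[0,1)$; a negative moment estimate
  is floored at 0 with a warning. The scale parameter is fixed at 1 for
  the binomial-variance family and moment-estimated for Poisson. The
  log-binomial family reuses the MLE's step-halving constraint. With
  singleton clusters the fit reduces to the independence GLM to
  numerical precision.

One caveat found while validating: the identity "model-based ≈ robust
SEs under a correctly specified family" holds only in expectation; on a
single simulated dataset the two differ at the $O_p(n^{-1/2})$ level, so
the test suite checks closeness at large $n$ rather than equality.

## Synthetic-data generators

`scenario_spec()` + `gen_independent_binary()` /
`gen_clustered_binary()` / `gen_multinomial()` emulate the three
settings above with user-set coefficients, cluster structure and
covariate generators. Two design rules:

* **Bounded covariate supports only** (constant, binary, uniform), so
  the valid-probability restriction can be *decided* over the whole
  support before generation; a spec implying $\theta > 1$ anywhere is
  rejected with an error, never silently clipped. For multinomial specs
  the check is conservative (sum of per-category suprema), which can
  reject a technically valid spec but never admits an invalid one.
* **Rejection, not truncation, of cluster effects.** A drawn $u_i$ that
  would push any probability in its cluster past 1 is redrawn, and the
  rejection count is attached to the dataset so the distortion of the
  nominal $N(0,\sigma_u^2)$ law is visible. Because the fixed part is
  validated to satisfy $\max\eta \le 0$, the per-draw rejection
  probability is at most 1/2 (symmetry of $u$); the >50%-rate abort
  mentioned in the error message is therefore a defensive bound reached
  only through pathological inputs.

What the generators deliberately do *not* emulate: covariate
correlation, unbounded covariates, cluster-size informativeness,
longitudinal structure, missingness. Recovery and coverage results on
generated data therefore demonstrate correctness of the machinery under
the stated models, not robustness to real-data violations of them.

## Embedded fixtures and what they can(not) reproduce

Three published worked examples are embedded as `rr_fixture` objects,
each carrying a provenance note and a completeness tag:

* `kerry_bland_trial()` — a cluster-randomized trial's 2×2 marginal
  counts (341/429 vs 509/702), expanded to 1131 rows. The real
  per-doctor allocation was never published; `clusters = TRUE` attaches
  a synthetic round-robin scaffold of 34 doctors which carries
  essentially no between-doctor heterogeneity. Consequently the
  published GEE ICC (0.010) is *not reproducible*, the scaffold's GEE
  $\alpha$ moment estimate is typically negative (floored at 0), and
  the mixed model's posterior ICC sits at the prior's lower boundary.
  The intervention RR, by contrast, is marginal-count arithmetic and
  reproduces well in every method.
* `adhf_margins()` — a 65-patient heart-failure cohort: aggregate
  margins (15 deaths), two published patient covariate rows and the
  published coefficient vectors. Row-level covariates are unavailable,
  so the full fits are not reproducible; what is reproducible — and
  tested — is the direction-level behaviour: the unconstrained Poisson
  coefficients predict probabilities above 1 for both published
  patients, the constrained model's cannot.
* `birthweight_margins()` — the classic 189-birth cohort's four
  birth-weight category counts (59/38/83/9; reference 3–4 kg). The
  row-level covariates are not vendored (provenance), but the marginals
  determine an intercept-only log-multinomial fit, exposed via
  `as_multinomial_data()`, whose exponentiated intercepts recover the
  category shares.

## Problem sizes and numerical tolerances used in validation

All validation is statistical, with explicit Monte-Carlo error bands:

* the intercept-only posterior is compared to a 400k-point grid
  quadrature of the truncated 1-D posterior, in mean (within
  3 autocorrelation-aware MCSEs) and 95% equal-tail endpoints (within
  3 quantile SEs);
* parameter recovery runs one fit per family at $n = 500$–$600$ rows
  (tests) and $n = 3000$–$20000$ (acceptance script), sized so a single
  replicate's sampling noise is a few percent of the target RR;
* interval coverage uses 200 replicates at $n = 300$ with reduced chain
  settings (2 × 1000 retained), accepting empirical coverage in
  $[90\%, 99\%]$;
* closed-form identities (2×2 RR and SE, singleton-cluster GEE, $J=2$
  multinomial/binomial equivalence) are checked at $10^{-8}$–$10^{-12}$.

## Known limitations

* Pure-R sampler: a week-scale production run of a 12,879-row multilevel
  model is feasible but slow; the package targets correctness and
  moderate problem sizes.
* No HPD intervals, no rank-normalized split R-hat, no Gibbs/HMC.
* The mixed-model constraint is observed-cluster (see above);
  predictions for *new* clusters at $u = 0$ can exceed 1 for covariate
  rows outside the observed support, and are reported as-is.
* Aggregate-only fixtures refuse row-level operations by construction;
  refits of the original row-level analyses require the user to supply
  those classic datasets.
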