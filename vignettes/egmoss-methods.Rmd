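---
title: "Stress-strength reliability inference with the EGMO family: models, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-strength reliability inference with the EGMO family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egmoss)
```

## The model

The exponentiated generalized Marshall-Olkin (EGMO-G) family transforms a
baseline distribution $G$ with survival function $\bar G$ in three stages:
a Marshall-Olkin tilt with parameter $\vartheta > 0$,
$\bar G \mapsto \vartheta\bar G / (1 - \bar\vartheta \bar G)$ with
$\bar\vartheta = 1 - \vartheta$; an inner power $a > 0$; and an outer power
$b > 0$:

$$F(x) = \Bigl\{1 - \Bigl[\frac{\vartheta\bar G(x)}{1 - \bar\vartheta\bar
G(x)}\Bigr]^{a}\Bigr\}^{b}, \qquad x > 0 .$$

`egmoss` ships Weibull (`par = c(shape, scale)`, survival
$e^{-(x/\beta)^\gamma}$) and exponential (`par = rate`) baselines; any other
baseline can be plugged in through the `egmo_baseline` contract (density,
cdf, survival, quantile and parameter derivatives). At
$a = b = \vartheta = 1$ the family collapses onto its baseline, which the
test suite uses as an exact oracle. $\vartheta > 1$ is permitted (the
denominator $1 - \bar\vartheta\bar G = G + \vartheta\bar G$ is a sum of
non-negative terms for every $\vartheta > 0$, which is also how it is
computed).

For stress $X \sim$ EGMO-G$(a, b_1, \vartheta, \lambda)$ and strength
$Y \sim$ EGMO-G$(a, b_2, \vartheta, \lambda)$ sharing all parameters except
the outer power, the stress-strength reliability has the closed form

$$R = P(Y < X) = \frac{b_1}{b_1 + b_2},$$

which is the quantity every estimator in the package targets.

## Random generation

Draws are produced by inversion. Solving $F(x) = u$ gives
$t = (1 - u^{1/b})^{1/a}$ and the baseline survival target
$\bar G^\* = t / (\vartheta + \bar\vartheta t)$, so
$Q(u) = Q_G(1 - \bar G^\*)$. (A commonly quoted variant of this inversion
with inner ratio $\vartheta(1-t)/(\vartheta + \bar\vartheta(1-t))$ does not
satisfy $F(Q(u)) = u$ for $\vartheta \ne 1$; the implementation uses the
algebraically correct form and the suite enforces the round trip to 1e-9.)

## Numerical representation

All distribution arithmetic is done in log space. With $z$ the baseline
cumulative hazard, the tilt ratio is $r = 1 - G/D$, $D = G + \vartheta e^{-z}$,
computed as `log r = log1p(-G/D)` — the naive form
$\log\vartheta - z - \log D$ loses all precision once $z \ll \epsilon
\vartheta$, which manifests as enormous spurious likelihood values.
$\log(1 - r^a)$ uses the standard $\log(2)$ crossover (`expm1` above it,
`log1p(-exp(\cdot))` below, and the first-order tail $-e^{a\log r}$ in the
deep tail), so outer exponents $b - 1 < 0$ remain stable as $r \to 1$ and
the quantile/cdf round trip holds to $10^{-9}$ across the unit interval.

## Maximum likelihood: why the search is box-constrained and screened

The EGMO likelihood is *unbounded* along several limiting ridges: $a \to 0$,
$b \to \infty$ with $\vartheta \to 0$, and $\vartheta \to \infty$ each
collapse the five-parameter family onto a three-parameter limit, and along
the way the density can pile unbounded mass onto one or two observations.
On real data these ridges re-enter the search region as "spike" local
maxima whose fitted cdf bears no resemblance to the data (order-of-magnitude
larger Kolmogorov-Smirnov distances at likelihood values far above any
adequate fit).
Reported maximum-likelihood estimates for this family are therefore
meaningful only as *selected local maxima*, and the package makes the
selection rule explicit:

1. **Box constraints.** Shape parameters ($a$, $b$, $\vartheta$, Weibull
   $\gamma$) are searched over $[10^{-2}, 10^{2}]$ on the log scale; scale
   parameters over a data-adaptive window (0.05-0.95 sample quantiles
   widened threefold; exponential rates over $[10^{-2}, 10^{2}]/\bar x$).
2. **Profiling.** $b$ (and in the two-sample model $b_1, b_2$) is profiled
   out in closed form, $\hat b = -n / \sum_i \log\{1 - r(x_i)^a\}$.
3. **Multi-start.** L-BFGS-B from `starts` points (default 50): the box
   centre plus log-uniform draws, generated from a *fixed default seed* so
   the estimator is a deterministic function of the data. The seed and
   start count are tuning constants of the optimizer, not sources of
   statistical randomness.
4. **Adequacy screen.** Candidate optima whose fitted cdf has a naive
   one-sample KS p-value below $10^{-3}$ are rejected as degenerate spike
   solutions. The threshold is a gross-consistency guard two orders of
   magnitude below conventional test levels; it does not act on honestly
   poor sub-models (those are reported with their poor KS), only on
   candidates *within* a model's own multi-start pool.
5. **Interior preference.** Among screened candidates the best one at
   least 0.25 log-units from every box bound is preferred; if none exists
   the best screened boundary solution is returned with
   `boundary = TRUE`, and if nothing passes the screen the best candidate
   is returned flagged `degenerate = TRUE`.

Even so, on flat ridge sections the outer power $b$ is only weakly
identified: near-equal log-likelihoods occur at widely different $b$.
Quantities that depend on $b$ through a single
sample — notably the plug-in reliability below — inherit this fragility,
which is documented rather than hidden.

Observed information is computed by central finite differences of the full
log-likelihood (relative step $10^{-4}$) at the reported optimum; standard
errors are shown where the matrix is invertible with positive diagonal of
the inverse.

## Joint versus plug-in estimation of R

`fit_egmo_ss(method = "joint")` maximizes the two-sample likelihood with
$(a, \vartheta, \lambda)$ shared — the model under which $R = b_1/(b_1+b_2)$
actually holds — profiling both $b$'s. `method = "plugin"` fits the full
EGMO model to each sample separately and plugs the two $\hat b$'s into $R$;
this is the common applied shortcut, and it is the procedure that published
stress-strength analyses of these datasets actually used (their per-sample
estimate ratios reproduce the published $\hat R$ values exactly). When the
two samples genuinely share shape and scale structure the two methods
agree; when they do not (the epidemic death and recovery rates differ in
scale by a factor of twenty), the joint model forces $R$ toward a boundary
and the plug-in value depends on per-sample branch selection — neither
number should then be over-interpreted.

The delta-method interval is
$\hat R \pm z_{1-\delta/2}\, \hat b_1\hat b_2 (\hat b_1+\hat b_2)^{-2}
\sqrt{1/n + 1/m}$, clipped to $[0,1]$ (clipping is flagged); the percentile
bootstrap resamples both samples independently with replacement, refits
warm-started from the full-data estimate, redraws failed refits (erroring
if more than 20% fail), and takes empirical percentiles.

## Bayesian estimation

Independent gamma priors are placed on $(b_1, b_2, \vartheta, a,
\lambda_k)$; the posterior updates Gamma$(n+\eta_1, H_1)$ etc. fix the
convention *shape* $=\eta$, *rate* $=\xi$, with
$H_1 = \xi_1 - \sum_i \log\{1 - r(x_i)^a\}$ and its companions computed by
`posterior_hyper()`.

The sampler (`egmo_ss_bayes`) runs Gibbs-within-Metropolis sweeps and
records $R^{(t)} = b_1^{(t)}/(b_1^{(t)}+b_2^{(t)})$; the squared-error-loss
estimate is the chain average (burn-in 0 by default, configurable). Two
modes are provided:

* `mode = "paper"` (default) uses the literature's gamma pseudo-conditionals
  for $b_1, b_2, \vartheta, a$ — note these drop likelihood factors that
  depend on $\vartheta$ and $a$, so the chain is *not* an exact posterior
  sampler; it is retained because published estimates derive from it.
* `mode = "exact"` replaces the $\vartheta$ and $a$ updates with
  random-walk Metropolis steps on the exact full conditionals.

Three degeneracies of the literal pseudo-conditional scheme are handled
explicitly, because chains provably collapse otherwise:

* the $\lambda_k$ update always targets the **exact** full conditional.
  The quoted marginal $\propto \lambda^{\eta-1}e^{-\xi\lambda + H_4}$ omits
  the $\lambda$-dependence inside $b_1H_1 + b_2H_2 + aH_3$ (by the identity
  $\log L(\lambda) = -b_1H_1 - b_2H_2 - aH_3 + H_4 + \text{const}$) and
  diverges as the baseline scale shrinks;
* $\xi_3 = 0$ makes the $\vartheta$-conditional Gamma$(\cdot, 0)$
  improper, so $\vartheta$ is held at its initial value;
* with a *fully* improper prior (all $\xi = \eta = 0$) the $a$ and
  $\lambda$ pseudo-updates also degenerate ($a \to 0$ feeds back through
  $H_3 \approx \sum z$ into a collapsing scale), so the sampler reduces to
  the known-parameter form: shared parameters stay at their initial
  joint-MLE values and only $b_1, b_2$ are Gibbs-drawn.

Prior layouts that specify four (rate, shape) pairs for a five-parameter
model are common in this literature; `sample_baseline = FALSE` implements
that reading by holding the baseline parameters at their initial joint-MLE
values (exactly as the fully non-informative reduction is forced to do)
while `(b_1, b_2, \vartheta, a)` are updated under their stated priors.
The default samples everything.

Chains start at the joint MLE; Gaussian random-walk proposals (negative
proposals rejected outright) are scale-adapted in batches of 50 during the
first $\min(T/2, 1000)$ sweeps towards 20-45% acceptance. All updates are
driven by one seed, so chains are exactly reproducible.

With known shared parameters the posterior of $R$ is available in closed
form. For $b_1 \sim$ Gamma$(\alpha_1, h_1)$, $b_2 \sim$
Gamma$(\alpha_2, h_2)$ independently,

$$E\Bigl[\frac{b_1}{b_1+b_2}\Bigr] = (1-\psi)^{\alpha_1}\,
\frac{\alpha_1}{c}\; {}_2F_1(c, \alpha_1+1; c+1; \psi), \qquad
c = \alpha_1 + \alpha_2,\; \psi = 1 - h_1/h_2,$$

derived by the $(w_1, w_2) = (b_1/(b_1+b_2), b_1+b_2)$ change of variables
and Euler's integral; for $\psi < 0$ the Pfaff transformation maps the
series argument back into $(0,1)$. The series is summed in log space with a
term-ratio stopping rule and falls back to adaptive quadrature on failure
(`bayes_closed_form`). The same reduction gives the F-distribution credible
interval implemented in `cred_int_F` (from
$2H_ib_i \sim \chi^2_{2(\cdot)}$), which the suite checks against $10^6$
product-gamma draws to three decimals.

## The Monte Carlo study driver

`run_mc_study()` generates stress/strength pairs by inversion at a true
parameter set, fits every requested estimator per replicate, and aggregates
estimates, MSE against the true $R$, and mean interval endpoints/lengths
per (n, m) cell. Replicate seeds are derived from the master seed by a
counter scheme (`seed*10^4 + cell*10^3 + replicate`), so any single cell
can be re-run in isolation; replicates whose fit fails are excluded and
counted. The package's test suite runs the study at 100 replicates with
per-replicate chains of length 300 and sizes (10, 30, 80) — sizes chosen
so the whole suite stays interactive — and verifies the qualitative
conclusions (MSE and all interval lengths decrease with sample size);
full-scale runs (1000 replicates, B = 1000, T = 1000) are a single
argument change.

## What the synthetic generator does and does not emulate

`make_synthetic()` draws i.i.d. EGMO samples with shared $(a, \vartheta,
\lambda)$ and known true $R$ — exactly the assumption under which every
estimator here is derived. Real stress/strength pairs (the packaged fibre
and epidemic-rate datasets among them) need not share shape parameters
across samples, may be serially dependent (the epidemic rates are a
smoothly evolving time series, not an i.i.d. sample), and may sit in
parameter regions where $b$ is weakly identified. Passing tests on
synthetic data therefore validate the estimators *under the model*, not
the model's appropriateness for any particular dataset.

## Goodness of fit

`egmo_compare()` fits the nested hierarchy (EGMO, EG ($\vartheta=1$), GMO
($a=1$), EMO ($b=1$), G ($a=\vartheta=1$), MO ($a=b=1$), baseline) by the
same screened multi-start machinery and tabulates log-likelihood,
AIC $= 2k - 2\log L$, BIC $= k\log n - 2\log L$, and the KS statistic
computed at both one-sided empirical-cdf jumps (ties handled by cumulative
counts) with the asymptotic Kolmogorov p-value — no small-sample or
parameter-estimation (Lilliefors-type) correction, matching how such
tables are conventionally reported. Nesting is verified in the tests:
every sub-family's maximized log-likelihood is no greater than its
super-family's, up to optimizer tolerance. Because the extra EGMO
parameters buy little on the packaged datasets, the parsimonious
sub-models often win on AIC; the comparison reports whatever the criterion
says.

## Known limitations

* Local-maximum selection is explicit but unavoidable: a different start
  budget can select a different ridge branch, and single-sample $\hat b$'s
  (hence plug-in $\hat R$) can move substantially while the maximized
  log-likelihood barely changes.
* `mode = "paper"` chains are not exact posterior samplers (documented
  above); use `mode = "exact"` for inference you intend to trust.
* The naive KS p-values are optimistic when parameters are estimated from
  the same data.
* Censoring is not supported, and only percentile bootstrap intervals are
  provided.
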