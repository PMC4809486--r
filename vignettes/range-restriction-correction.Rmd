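---
title: "Correcting predictive validity for range restriction with a dichotomous criterion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting predictive validity for range restriction with a dichotomous criterion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When applicants are selected top-down on a test score, the criterion
("successful" / "not successful") is observed only for those admitted. The
selected sample is not a random sample of the applicant pool, so the sample
correlation between the predictor $X$ and the criterion $Y$ underestimates
the predictive validity, and the selected sample's *success rate*
overestimates the *base rate of success* (BR), the proportion of all
applicants who would have succeeded. validmi implements and evaluates two
ways to undo this distortion when the criterion is dichotomous:

1. **Classical sd-ratio corrections.** Under direct restriction (selection
   on $X$ itself, "Case 2") the corrected correlation is
   $$\rho_{XY} = \frac{k\,r_{XY}}{\sqrt{1 + r_{XY}^2 (k^2 - 1)}},
   \qquad k = S_X / s_X,$$
   with $S_X$, $s_X$ the unrestricted and restricted standard deviations of
   the selection variable. Under indirect restriction (selection on a third
   variable $Z$, "Case 3") the analogous three-correlation formula in
   $k = S_Z / s_Z$ applies (`correct_drr()`, `correct_irr()`). Both exist for
   continuous criteria; applying them to a dichotomous $Y$ leaves two gaps:
   the success proportion of the selected sample is biased (which distorts
   any biserial conversion) and neither formula estimates the BR at all.
2. **A missing-data correction.** Selection is a *missing-at-random*
   mechanism: the probability that $Y$ is missing depends only on the fully
   observed selection variable. The package therefore imputes the missing
   criterion values with Bayesian logistic regression — fit
   $\Pr(Y_i = 1 \mid x_i, \beta) = \mathrm{logit}^{-1}(x_i'\beta)$ on the
   observed rows, draw $\beta^\ast$ from the approximate posterior, impute
   each missing $Y_i$ as Bernoulli with its fitted probability — repeated
   $m$ times, and pools each statistic (correlation, BR) as the arithmetic
   mean of the $m$ completed-data estimates (`multiple_impute()`,
   `mice_estimate()`). Because $Y$ is the only incomplete variable, the
   chained-equations cycle collapses to this single conditional model.

Two kinds of dichotomy are distinguished throughout. A *natural* dichotomy
(e.g. graduated vs not) is summarized by the point-biserial correlation
$\rho_{pb} = (M_1 - M_0)\sqrt{pq}\,/\,\sigma_X$. An *artificial* dichotomy
(a continuous trait split at a cut-off) is summarized by the biserial
correlation $\rho_b = \rho_{pb}\sqrt{pq}/h$, which estimates the latent
Pearson correlation; $h$ is the standard normal ordinate at the split and
$p, q$ the category proportions. Both coefficients shrink as $p$ moves away
from $.5$ — which is exactly why a correction that only sees the selected
sample's success proportion remains biased, and why the imputation route,
which re-estimates $p, q$ on completed data, can do better.

## What the generators emulate

`simulate_population()` produces applicant pools of the two designs used in
the evaluation:

* **Artificial dichotomy**: a bivariate (direct) or trivariate (indirect)
  standard normal with target correlations; the latent criterion is split
  at $\Phi^{-1}(1 - \mathrm{BR})$, so values above the cut are successes.
  At BR = .5 the cut sits at 0.
* **Natural dichotomy**: $Y \sim \mathrm{Bernoulli}(\mathrm{BR})$ i.i.d.,
  and $X$ (and $Z$) are unit-variance normals whose means differ between
  the criterion groups by $d$. The implied marginal sd is
  $\sqrt{1 + \mathrm{BR}(1-\mathrm{BR})d^2}$ (`mixture_sd()`), and $d$ is
  chosen by inverting the implied point-biserial correlation
  (`d_from_pb()`); e.g. $d = 1.5$ at BR = .5 gives $\sigma_X = 1.25$ and
  $\rho_{pb} = .60$. Group membership is drawn i.i.d. rather than as fixed
  counts: an applicant population's realized base rate is itself random,
  as in real selection settings.

For the indirect natural design the within-group $X$–$Z$ correlation is not
free: `solve_within_corr()` sets
$\rho_w = \rho_{ZX}\sigma_X\sigma_Z - \mathrm{BR}(1-\mathrm{BR})d_Xd_Z$ so
the marginal $Z$–$X$ correlation hits its target; combinations implying
$|\rho_w| \ge 1$ are infeasible and are rejected and redrawn, as are
non-positive-definite latent correlation matrices (`draw_factors()` logs
the rejection count).

What the generators deliberately do **not** emulate: non-normal (skewed,
heavy-tailed) predictors, measurement error in $X$ or $Z$, more than three
variables, and any selection rule other than deterministic top-down
truncation. Monte Carlo results under these generators therefore speak to
the idealized MAR setting, not to self-selection (MNAR) or unmeasured
selection variables.

## Selection and exclusions

`restrict_sample()` sorts descending on the selection variable and keeps
$\mathrm{round}(N \cdot \mathrm{SR})$ criterion values (rounding half away
from zero; the predictor and selection variables stay observed for
everyone). A restricted sample supports a valid logistic fit only if both
criterion categories are observed; following the contingency-table rule of
thumb, `passes_marginal_condition()` requires at least five observed cases
per category, and Monte Carlo samples failing it are excluded — for *both*
methods, so precision comparisons stay paired on identical samples. The
same pairing applies to the (rare) samples whose imputation fit does not
converge and to degenerate draws.

## Numerical choices

* **Logistic fit** (`fit_bayes_logistic()`): Newton/IRLS with step-halving
  on a ridge-penalized log-likelihood (ridge $10^{-5}$, iteration cap 150,
  relative coefficient tolerance $10^{-6}$). The posterior is approximated
  as normal at the penalized MLE with the inverse penalized information as
  covariance; `draw_beta()` samples it via Cholesky, flooring negative
  eigenvalues at zero in the (rare) semi-definite case.
* **Separation guard** (`stabilize = TRUE`): heavily restricted samples can
  be (quasi-)separated. Following the weighted-augmentation device of
  White, Daniel & Royston — the default behavior of the standard
  multiple-imputation logistic method — the fit adds, per predictor, one
  pseudo success and one pseudo failure at the predictor's mean $\pm$ half
  an sd (computed over all applicants, clipped to the observed range), with
  total pseudo-weight $p + 1$. This keeps fits finite and slightly shrinks
  extreme slopes. It is part of the procedure being evaluated, not a
  nuisance fix: the guard materially shapes the imputation route's bias
  under heavy restriction and its precision elsewhere, so results with
  `stabilize = FALSE` describe a different estimator.
* **Ordering of correction and biserial conversion** (artificial
  dichotomies): the restricted correlations involving the criterion are
  first converted to biserial form using the selected sample's success
  proportion — the only proportion the classical route can see — and the
  sd-ratio correction is then applied to them. We adopted this ordering
  (rather than correcting the point-biserial first) because it is what
  applying the classical formulas to the observed coefficient means
  operationally — the biserial *is* the observed validity coefficient for
  an artificial dichotomy. The ordering matters: converting afterwards
  instead largely cancels the base-rate-driven bias of the classical
  route, i.e. it describes a different (and less commonly used)
  estimator.
* **Out-of-range estimates**: biserial values and indirect corrections that
  leave $[-1, 1]$ in finite samples are clipped to $\pm 1$ and flagged
  (`clipped`), keeping residuals bounded.
* **Pooling**: arithmetic means; a set of identical per-imputation values
  pools to that value exactly, so full selection is a bit-for-bit no-op.
* **Reproducibility**: every Monte Carlo iteration reseeds from a child
  seed derived deterministically from the master seed, so any single cell
  can be reproduced in isolation and a run is a pure function of its
  configuration.

## The evaluation framework

`run_condition()` crosses a scenario (direct/indirect) and a criterion
kind, drawing the correlations and BR uniformly on $[.1, .9]$ per
iteration, and records per selection ratio the residual of each estimator
against the *unrestricted sample's* statistics (`true_params()`): the
biserial for artificial dichotomies, the point-biserial for natural ones,
and the BR for the imputation route. `accuracy_summary()` reports the mean
error (trueness; positive = overestimation) and RMSE (precision) per cell,
and `f_ratio_summary()` the precision ratio
$F = \mathrm{MSE}_{\text{sd-ratio}} / \mathrm{MSE}_{\text{imputation}}$ on
paired residuals, with a one-sided upper-tail p-value on an F distribution
whose degrees of freedom are the usable iteration counts per group (the
reference analysis reports only significance levels; df and sidedness are
this package's documented choice). True correlations can be partitioned
into weak $[.10, .40)$, moderate $[.40, .70)$ and strong $[.70, .90]$
relationships (`partition_by_strength()`); sample truths drifting outside
$[.1, .9]$ are dropped from partitioned summaries. Cells with fewer than
100 usable iterations are flagged unstable.

`preliminary_m_study()` examines the number of imputations $m$ at fixed
missing rates under direct selection. Within each iteration the imputation
model is fitted once and $\max(m)$ completed datasets are drawn; the pooled
estimate for each $m$ uses the first $m$ of them, so the $m$-comparison is
paired and the reported change from $m = 20$ to $m = 50$ is not swamped by
between-iteration noise. Pairing is the package's design choice; it does
not change any single-$m$ distribution.

### Problem sizes

The package's own checks run each condition at 500–1000 iterations of
$N = 500$ populations with $m = 20$ imputations; `run_condition()` itself
defaults to 5000 iterations for full-scale studies. At
1000 iterations the Monte Carlo standard error of a mean-error cell is
about $.003$–$.01$ depending on the selection ratio, which is why the
package's accuracy checks carry absolute tolerances of $.01$–$.02$.

## Known limitations

* The precision F-ratio at the most extreme selection ratios is
  floor-limited: the pooled point estimate retains an irreducible error
  from replacing realized Bernoulli outcomes by model draws (not reduced
  by $m$) plus coefficient-estimation noise from the truncated fit. At
  SR $\ge .8$ both components are of the same order as the total error,
  so F-ratios there are sensitive to small differences between
  implementations of the imputation engine and should be read as orders
  of magnitude, not precise values.
* With 90% missing criterion data the imputation route still underestimates
  the validity (mean error about $-.1$); estimates under such heavy
  restriction should be interpreted cautiously whatever the method.
* The normal-approximation posterior replaces the exact Bayesian draw; at
  the sample sizes involved ($\ge 50$ observed cases after the exclusion
  rule) the approximation error is dominated by Monte Carlo noise.
* Rubin-style between/within variance pooling (confidence intervals) is out
  of scope; only point estimates are pooled.

## A worked call

```{r example}
library(validmi)

set.seed(7)
pop <- simulate_population(500, "DRR", "natural", rho_xy = 0.5, br = 0.6)
true_params(pop)            # unrestricted sample truth
sel <- restrict_sample(pop, sr = 0.4)
fit <- correct_validity(sel, kind = "natural", seed = 1)
tidy(fit)                   # both corrections side by side
glance(fit)                 # sample sizes, success rate, sd ratio

# a small Monte Carlo condition
run <- run_condition("DRR", "natural", iterations = 200,
                     sr_grid = c(0.2, 0.5, 0.8), seed = 1)
tidy(run)
autoplot(run)
```
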