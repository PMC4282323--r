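---
title: "Estimating the selected treatment mean in drop-the-loser trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the selected treatment mean in drop-the-loser trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtlshrink)
set.seed(1)
```

## The problem

A two-stage drop-the-loser trial screens $k$ experimental treatments in a
first stage, carries only the best-performing arm forward, and re-estimates
that arm on an independent second-stage population.  Write
$X_i \sim N(\mu_i, \sigma_1^2)$, $i = 1, \dots, k$, for the stage-1 effect
estimates (the variance $\sigma_1^2$ is common and treated as known),
$s = \arg\max_i X_i$ for the selected arm, and
$Y_s \sim N(\mu_s, \sigma_2^2)$ for its stage-2 estimate.  The natural
point estimate of $\mu_s$,

$$\hat\mu_s^{\mathrm{MLE}} \;=\;
  \frac{X_s/\sigma_1^2 + Y_s/\sigma_2^2}{1/\sigma_1^2 + 1/\sigma_2^2},
  \qquad
  \tilde\sigma^2 = \Bigl(\tfrac{1}{\sigma_1^2} +
  \tfrac{1}{\sigma_2^2}\Bigr)^{-1},$$

ignores the fact that arm $s$ was chosen *because* $X_s$ was the largest,
and is therefore positively biased — most severely when the true means are
all equal, where nothing but noise drives the selection.  `dtlshrink`
implements this MLE together with six competing estimators that either
remove the selection bias outright or trade a little bias for a much
smaller mean squared error, and a Monte Carlo engine that measures all of
them under controlled scenarios.

Only $\mu_s$ is modelled.  A control arm proceeding to stage 2 alongside
the winner is estimated without selection, so its MLE is unbiased and the
contrast is a trivial subtraction; the package leaves it out.

## The estimators

**UMVCUE.**  Rao–Blackwellising the unbiased stage-2 estimate against the
sufficient statistic and the selection event $X_s \ge X_r$ (where $X_r$ is
the runner-up stage-1 estimate) gives

$$\hat\mu_s^{U} \;=\; Z -
  \frac{\sigma_2^2}{\sqrt{\sigma_1^2 + \sigma_2^2}}
  \frac{\phi(v)}{\Phi(v)}, \qquad
  v = \frac{\sqrt{\sigma_1^2 + \sigma_2^2}}{\sigma_1^2}\,(Z - X_r),$$

with $Z$ the combined MLE.  It is exactly unbiased given the selection, for
*any* configuration of true means, but pays for this with the largest
variance of all seven estimators at realistic $k$.

**Carreras–Brannath shrinkage (`cb`).**  Stage-1 estimates alone feed
Lindley's equal-variance shrinkage towards their unweighted mean,
$L_s = \bar X + C^+ (X_s - \bar X)$ with
$C = 1 - (k-3)\sigma_1^2 / \sum_j (X_j - \bar X)^2$, and $L_s$ then replaces
$X_s$ in the precision-weighted combination with $Y_s$.  Under an i.i.d.
normal prior on the $\mu_i$ this dominates the MLE in MSE.  We store the
factor multiplying the deviation $(X_s - \bar X)$; note that the same
estimator is sometimes written with "the shrinkage factor" naming the
complementary quantity $1 - C$ (the amount of shrinkage), in which case
"factor zero" describes the no-shrinkage limit where the estimator
coincides with the MLE.  The algebra is identical either way.

**The meta-analytic view.**  Using *all* the data in a single shrinkage
equation means working with $k$ estimates of unequal known variance:
$\tilde X_i = X_i$ with $W_i = \sigma_1^2$ for the dropped arms, and
$\tilde X_s = Z$ with $W_s = \tilde\sigma^2$ for the winner.  This is
precisely the setting of a fixed/random-effects meta-analysis of $k$
"studies", and the remaining estimators are built from its standard
machinery, exposed in the package as stand-alone functions:
`generalized_q()` ($Q(\tau^2) = \sum_i (\tilde X_i - \hat\mu_V)^2 / V_i$,
$V_i = W_i + \tau^2$), `paule_mandel_tau2()` (solve $Q(\tau^2) = k - 1$,
truncate at 0), `dersimonian_laird_tau2()` (closed-form moment estimator
plus $I^2$), `fixed_effect_mean()`, and `profile_loglik_tau2()` /
`maximize_profile_tau2()`.

**Direct plug-in (`direct`).**  With $\mu_i \sim N(\mu, \tau^2)$ the oracle
posterior mean of $\mu_s$ is
$(\tau^2 \tilde X_s + W_s \mu)/(W_s + \tau^2)$.  The direct estimator plugs
in the profile-likelihood maximiser $\hat\tau^2$ and the weighted mean
$\hat\mu(\hat\tau^2)$.  At $\hat\tau^2 = 0$ it collapses to the
fixed-effects grand mean — superb when the true means really are close
together, and badly wrong when the selected arm is a genuine outlier.

**Carter–Rolph standard prior (`cr_standard`).**  Approximates the same
posterior mean with an explicit shrinkage form:
$\hat\mu + C^+(\tilde X_s - \hat\mu)$ with Paule–Mandel $\hat\tau^2$, the
random-effects grand mean, and

$$C = 1 - \frac{k-3}{k-1}\,\frac{W_s}{W_s + \hat\tau^2_{PM}}.$$

When all $W_i$ are equal and the moment equation has a positive root this
reduces exactly to Lindley's factor; when $\hat\tau^2_{PM} = 0$ it keeps
the floor $1 - (k-3)/(k-1)$, so the estimate never collapses all the way to
the grand mean.  That floor is why it behaves so well when the means are
truly equal.

**Carter–Rolph proportional prior (`cr_proportional`).**  Assuming prior
variances proportional to the sampling variances,
$\mu_i \sim N(\mu, W_i\tau^2)$, makes the posterior shrinkage weight common
across arms and removes $\tau^2$ estimation entirely:
$C = 1 - (k-3)/Q(0)$ around the *fixed-effects* mean, with $Q(0)$
Cochran's heterogeneity statistic.  The price is conceptual: the prior for
$\mu_s$ can only be written down after seeing which arm won, a violation of
temporal coherency that practitioners may or may not accept.

**Limited translation (`cr_proportional_lt`).**  The proportional-prior
estimate clipped to $[\,\tilde X_s - c\sqrt{W_s},\; \tilde X_s +
c\sqrt{W_s}\,]$, protecting an extreme selected arm from over-shrinkage.
The corridor half-width $c$ defaults to one naive standard error — the
usual practical choice — and is exposed as `lt_width` because the optimal
width under selection is an open problem; we deliberately do not tune it.

All factor-based methods apply the plus-rule ($C^+ = \max(C, 0)$)
uniformly: the published account states it for the equal-variance factor,
and the unequal-variance factors can go negative in exactly the same way,
where a negative multiplier would no longer be shrinkage at all.  Degenerate
zero-dispersion stage-1 data give $C^+ = 0$ and an estimate equal to the
common value.  Shrinkage constants contain $(k-3)$, so these methods need
$k \ge 4$; `small_k_fix = TRUE` substitutes $(k-2)$ at $k = 3$, a crude but
conventional patch.  The direct plug-in works from $k \ge 2$.

```{r single-trial}
design <- dtl_design(k = 6, sigma1 = 1, sigma2 = 1)
outcome <- dtl_outcome(x = c(0, 0, 0, 0, 0, 3), y_s = 1)
estimate_all(outcome, design)
```

## The simulation engine

`run_scenario()` draws the $k$ true means, simulates both stages, applies
the selection rule ($\arg\max$, ties to the lowest index — a
probability-zero event under the model, fixed only for determinism), and
accumulates each estimator's error against the *realised* $\mu_s$ of that
replicate.  At the trial outset $\mu_s$ is a random quantity — a mixture of
the $\mu_i$ weighted by selection probabilities — and bias and MSE are
defined against it, not against any fixed parameter.  Both are reported
scaled by $\tilde\sigma$ so that different variance settings are
comparable.

The four mean scenarios are the study conditions of the benchmark
comparison, with $k = 6$ and 50000 replicates as the reference
configuration:

* **I** — $\mu_i \sim N(0, \tau^2)$ redrawn every replicate ($\tau^2 = 1$
  by default): the setting in which the shrinkage priors are correct.
* **II** — all means equal: selection is pure noise and the MLE's bias is
  maximal ($E[\text{bias}] = m_k \tilde\sigma^2/\sigma_1^2$ analytically,
  with $m_k$ the expected maximum of $k$ standard normals — the engine is
  tested against this closed form).
* **III / IV** — one mean raised by $\delta = 1$ or $1.5$ above the rest:
  incompatible with every shrinkage prior, probing robustness.

`run_table1()` crosses the scenarios with a set of $(\sigma_1, \sigma_2)$
levels — $(1,1)$ and $(2,1)$ are the standard benchmark settings; the other
two default to $(1,2)$ and $(2,2)$ and are freely configurable —
and `dtl_sweep()` traces $\delta$, $\tau^2$ or $k$ along a grid.  Every
cell draws its own seed from the master seed, so any cell can be reproduced
in isolation.

Internally the engine is fully vectorised over replicates, including a
bisection Paule–Mandel solver and a coarse-grid-plus-golden-section profile
maximiser operating on replicate-by-arm matrices; a 50000-replicate,
seven-estimator scenario runs in a few seconds.  The per-trial functions
define the reference semantics and the test suite pins the two code paths
together replicate by replicate.

## Numerical choices

* Paule–Mandel: bracket $[0, 10\max(\mathrm{var}(\tilde X), \max W_i)]$,
  doubled up to 60 times, then root-finding to $|Q - (k-1)| < 10^{-8}$
  (scalar path `uniroot` at tolerance $10^{-12}$; batch path 90 bisection
  steps).
* Profile likelihood: the same expanding upper bound, a 33-point quadratic
  grid to localise the mode (the profile need not be unimodal far from the
  mode; the grid guards against stranding in a shoulder), then local
  refinement to $10^{-8}$ in $\tau^2$; a boundary maximiser at 0 is
  accepted.  We maximise the plain profile log-likelihood
  $-\tfrac12\sum_i [\log(W_i+\tau^2) + (\tilde X_i - \hat\mu(\tau^2))^2 /
  (W_i+\tau^2)]$; a joint $(\mu, \tau^2)$ maximisation could differ
  slightly at small $k$, and the surrounding code treats the
  heterogeneity fit as a swappable strategy should that variant ever be
  preferred.
* The Mills ratio $\phi/\Phi$ in the UMVCUE switches to its asymptotic
  expansion below $v = -30$, where `pnorm` underflows.
* The grand mean reported with a heterogeneity fit is always the
  inverse-$(W_i + \hat\tau^2)$-weighted mean at that fit's $\hat\tau^2$, so
  fixed- and random-effects means coincide whenever $\hat\tau^2 = 0$.

## What the simulations do and do not show

The generator reproduces the model exactly: known variances, a common
stage-1 standard error, independent normal estimates, selection purely by
the stage-1 maximum, and stage-2 data only for the winner.  Real trials
deviate from all of these — variances are estimated, arms can share a
control group (correlating the estimates), selection may weigh safety or
secondary endpoints, and effects need not be normal.  Passing benchmarks
here therefore validates the estimators *under their stated assumptions*,
not their behaviour under misspecification; the observed-trial reader
accepts a winner that is not the stage-1 maximum only with a warning,
because every bias-correction guarantee is void in that case.

The test suite runs reduced problem sizes (mostly $10^3$–$2\times 10^4$
replicates, with the headline benchmark cells at the full 50000) — the
choices balance Monte Carlo error against suite runtime and are stated in
each test.  Monte Carlo standard errors accompany every reported summary,
and stochastic assertions use three-standard-error bands.

```{r scenario, eval = FALSE}
run_scenario(dtl_design(6, 1, 1), "II", reps = 50000, seed = 7)
```

## Known limitations

Multi-stage (more than two) selection designs, correlated arms through a
shared control, unequal stage-1 variances and interval estimation are out
of scope.  The limited-translation corridor is fixed rather than tuned, and
no dominance guarantee exists for the meta-analytic estimators — the
Carreras–Brannath result covers `cb` only, and only in scenarios I and II.
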