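---
title: "Modelling volatility-adaptive reward learning with volatilearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling volatility-adaptive reward learning with volatilearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volatilearn)
```

## The task and its stated world

The package models a two-armed probabilistic reward task. On every trial
two options (call them A and B; on screen they are coloured chests) carry
complementary reward magnitudes — integers that always total 100 points —
and exactly one option is rewarded. Option A is defined as the option
most often rewarded during the initial stable phase. The *short* variant
presents 80 stable trials with A rewarded on exactly 75% of trials,
followed by 80 volatile trials in which the rewarded ratio alternates
between 20:80 and 80:20 every 20 trials (switches at trials 81, 101, 121
and 141). The *long* variant presents 120 stable trials at 75:25 and 170
volatile trials switching every 30 or 40 trials (30–40–30–40–30), with
the phase order configurable because sessions counterbalanced it. A
20-trial familiarization block at 80:20 is supported but excluded from
every analysis.

Two deliberate schedule conventions:

* **Exact-ratio realization.** Within each block the number of
  A-rewarding trials is exactly `round(length × p)` (rounded half-up),
  randomly placed. Fixed ratios make block-level structural checks exact;
  an i.i.d. Bernoulli scheme would only satisfy them in expectation.
* **Magnitudes.** The magnitude of A is an independent uniform integer in
  [0, 100]; B receives the complement. No other constraint is imposed,
  matching the task's description of freely varying flag values.

Trial indexing is 1-based and inclusive throughout.

## The ideal observer

The normative benchmark is a Bayesian filter that tracks three latent
variables from the outcome sequence alone: the reward probability
$r_t \in (0,1)$ of option A, its log-volatility $v_t$, and a static drift
parameter $k$ describing how fast volatility itself changes.

* $r_{t+1} \mid r_t, v_{t+1} \sim \mathrm{Beta}$ with mean $r_t$ and
  concentration $\exp(-v_{t+1})$ — larger $v$ means a more diffuse kernel,
  i.e. a more changeable environment;
* $v_{t+1} \mid v_t, k \sim \mathcal{N}(v_t, \exp(k)^2)$;
* $y_t \mid r_t \sim \mathrm{Bernoulli}(r_t)$, where $y_t$ indicates that
  A was rewarded.

Inference is exact discretized Bayes on a three-dimensional grid
(`init_posterior()`, `update_posterior()`, `run_observer()`). Each
filtering step propagates $v$ (per $k$ level), then $r$ (conditional on
the new $v$), multiplies the Bernoulli likelihood, and renormalizes.
Because magnitudes are random and uninformative about $r$, the observer
never sees them, nor any choices.

Numerical choices:

* **Cell-integrated kernels.** Transition matrices hold the kernel's
  probability mass integrated over destination grid cells (CDF
  differences), not pointwise densities. At low volatility the beta
  kernel is narrower than the grid spacing and pointwise discretization
  aliases badly; cell masses remain exact and column-stochastic.
* **Grids.** Defaults: 30 points for $r$ on [0.01, 0.99], 15 for $v$ on
  [−7, −0.7] (concentration ≈ 2 to 1100), 15 for $k$ on [−4, 0.5]
  (random-walk SD ≈ 0.02 to 1.65). The ranges are generous rather than
  tuned; the resolutions were fixed once, by requiring that doubling all
  of them changes the posterior-mean trajectory by less than 0.01
  (sup-norm) on 160-trial schedules. The prior is uniform on the grid.
* **Alignment.** The exported trajectory value for trial $t$ is the
  posterior mean given outcomes $1..t{-}1$ — the quantity available when
  the trial-$t$ decision is made — so it is directly usable as a choice
  regressor. Mass is renormalized and checked after every step; underflow
  raises an error with grid diagnostics rather than returning garbage.

One behaviour worth knowing: after a long stable phase the marginalized
$k$ concentrates on slow drift, so the volatility estimate responds
conservatively to the first reversals. Across many schedule realizations
the volatile-phase mean of $E[v]$ exceeds the stable-phase mean in about
92% of seeds (the shortfall is the uniform prior's early transient plus
this deliberate sluggishness); the property is therefore asserted across
seeds, not per seed. Strict trial-by-trial outcome alternation does *not*
raise $E[v]$ — it is exactly what a stable fair coin produces, and the
filter correctly infers low volatility there. What raises $E[v]$ is
block-wise reversal, the structure the task actually uses.

## Synthetic agents: the data generator

`simulate_agent()` and `simulate_cohort()` generate choice data with
known ground truth, which is recorded alongside every cohort — there is
no unrecoverable synthetic data. The central agent is the
Rescorla–Wagner learner:

$$\hat r \leftarrow \hat r + \alpha\,(y - \hat r), \qquad \hat r_1 = 0.5,$$

with a logistic selector on the expected-value difference. Expected value
is probability × magnitude; since magnitudes are complementary the
decision variable reduces to

$$d_t = \frac{m_{A,t}}{100} + \hat r_t - 1 \in [-1, 1], \qquad
  P(\text{choose A}) = (1-\epsilon)\,\mathrm{logit}^{-1}(\beta d_t)
  + \epsilon/2.$$

**Selector scale.** $\beta$ operates on the unit-normalized difference
(dividing by the 100-point total). On the raw point scale even $\beta=5$
would be effectively deterministic, which would make moderate and extreme
temperatures indistinguishable; on the unit scale $\beta = 0$ is random
choice, $\beta \approx 5$ is realistically noisy and $\beta = 1000$ is
argmax. All likelihoods use the same convention, so fitted $\beta$ values
are comparable to generating ones.

The learning rate may differ between the stable and volatile phases
(`alpha = c(stable = .2, volatile = .4)`), which is how cohorts embodying
the core phenomenon — a learning rate that rises under volatility — are
generated. The lapse rate $\epsilon$ (default 0) exists to probe
estimator robustness and is not part of the core generative story.

Degenerate strategies for model-comparison tests: win-stay/lose-shift
(repeat after reward, switch otherwise; first choice random), strict
alternation (first choice random), value-following (pick the larger
magnitude; 50/50 ties broken at random), and random choice. The agents
update on the full trial outcome (which option was rewarded): the task
reveals the treasure's location on every trial, so even a wrong choice is
informative. Whether real participants exploit that fully is unknowable
from the task description; it is the single convention used throughout.

What the generator does **not** emulate: reaction times, attention or
fatigue drifts, subjective utility curvature, stickiness/perseveration
beyond WSLS, or social context. A green test therefore establishes that
the pipeline recovers what these idealized learners put in — not that
real participants behave like them.

## Strategy comparison GLM

`build_design()` codes four candidate strategies as simultaneous
regressors for a per-subject logistic GLM of choices (constant included):
the ideal observer, alternation, WSLS, and the reward value of option A
(z-scored). Binary strategy predictions are coded ±0.5 around the
constant; t-statistics are invariant to these affine codings. The first
trial has no previous choice, so alternation and WSLS are undefined there
and the trial is dropped.

**The ideal-observer regressor is the observer's decision variable**
$m_A/100 + E[r_A] - 1$, not the bare probability estimate. The observer
is a model of *choices*, and optimal choice weighs probability by
magnitude; a probability-only regressor systematically loses the
best-model contest to the value regressor even for data generated by
expected-value learners, because with uniform random magnitudes the
magnitude term carries at least as much unique choice variance as the
probability term by construction. With the decision-variable coding,
delta-rule cohorts are classified as ideal-observer for ≈95% of subjects
at high β, while value-followers still classify as value (their choices
ignore $E[r_A]$, so the pure magnitude column fits strictly better). The
probability-only coding remains available via
`ideal_regressor = "e_r"`.

`fit_choice_glm()` uses ridge-penalized maximum likelihood (penalty
λ = 0.01 on non-intercept coefficients, never the constant). The penalty
exists solely to keep perfect separation — guaranteed for deterministic
strategies — finite and well-defined; away from separation it shifts
t-statistics by well under 1%, and under the random agent the per-regressor
false-positive rate stays inside the 95% binomial band around .05 (checked
over 1000 simulated subjects). A strategy "fits" a subject when its
regressor's two-sided p-value (t distribution, residual df) is below .05;
p-values are uncorrected, matching how such proportions are convention-
ally reported. Rank-deficient designs drop the offending column with a
warning recorded in the result. "Best-fitting model" is reported both per
subject (argmax of t) and per group (argmax of mean t), since group-level
summaries are conventionally shown both ways.

## Learning-rate estimation

`choice_likelihood()` evaluates the delta-rule/selector model on a fixed
window: the predictor runs over *all* trials from trial 1 — the
participant experienced the pre-window trials, so they shape the
learner's state — but only window trials contribute likelihood terms.
Windows: trials 20–80 (stable) and 90–150 (volatile) in the short
variant (61 trials each); the last 81 trials of each phase in the long
variant. Choice probabilities are floored at $10^{-10}$ inside the log to
bound the objective.

`fit_learning_rate()` minimizes the negative log-likelihood jointly over
$(\alpha, \beta)$ — the predictor has a single free parameter, but a
proper likelihood needs the selector temperature as a jointly fitted
nuisance parameter — by L-BFGS-B with analytic gradients (the trace
sensitivity $\partial\hat r/\partial\alpha$ obeys the same first-order
recursion as the trace and costs one extra filter pass) from a fixed 5×5
start grid ($\alpha \in \{.02,.1,.3,.6,.9\}$,
$\beta \in \{.5,2,5,15,40\}$), bounds $\alpha \in [0.001, 0.999]$,
$\beta \in [0, 50]$. The fixed grid makes refits bit-identical. β is
fitted per window; nothing in the task description implies it is shared
across conditions.

The contrast $\Delta = \log\hat\alpha_{vol} - \log\hat\alpha_{stab}$
uses natural logs (the base only rescales test statistics). Parameter
recovery at the 61-trial window length keeps $|\mathrm{bias}(\log\hat\alpha)|
< 0.3$ for true $\alpha \in \{.1,.2,.4\}$ at $\beta = 5$; since $\Delta$
subtracts two window estimates, its recovery tolerance is the propagated
0.6. Both bounds are regression-tested. For a cohort whose true learning
rate doubles, the recovered group-mean $\Delta$ is positive, within 0.6
of $\ln 2$, and positive for over 80% of subjects; a null cohort's 95%
CI covers zero at ≥ 90% across simulated cohorts.

## Reversal slopes

`running_average()` is a *trailing* 4-trial mean: the value at trial $t$
averages trials $t-3..t$, so values exist for every trial of each
post-switch interval immediately after a switch — the only alignment for
which "the first ten running averages after the switch" (trials 101–110,
121–130, 141–150) is fully defined. `post_switch_slopes()` fits an OLS
line to those ten values against trial index; raw slope (probability per
trial, signed toward option A), absolute and square-root-transformed
values are returned. The square root is the conventional normalizing
transform before ANOVA on such slopes. An instant, perfect switcher
produces the running-average ramp .25, .5, .75, 1, 1, … whose OLS slope
is exactly 23/330 ≈ 0.0697 in every interval — the hand-computed oracle
frozen in the tests. The trial-81 condition boundary is not part of the
slope analysis; only the three within-volatile reversals are.

## Group statistics

`mixed_anova()` implements the classical univariate mixed-design
decomposition (one within-subject factor, optional one between-subject
factor) with partial η² per effect; with unequal group sizes it uses the
weighted-means decomposition, which coincides with the Type III tables of
standard software for the balanced designs this package generates (and
matched an independent reference implementation exactly on an unbalanced
check as well). Degenerate inputs (constant response) report F = 0,
p = 1 rather than NaN. `mauchly_sphericity()` and `repeated_contrasts()`
cover the sphericity check and successive-level contrasts; two-sample
t-tests switch to the Welch form automatically when the variance ratio
exceeds 2, mirroring the applied convention of reporting fractional
degrees of freedom only when needed. These are deliberately off-the-shelf
statistics, pinned by hand-computed fixtures and by `aov()`/reference
cross-checks in the test suite.

## Known limitations

* The ideal observer's grid bounds clip extreme reward probabilities at
  [0.01, 0.99]; schedules outside that range would need wider grids.
* The delta-rule likelihood assumes the unit-scale logistic selector; if
  an agent's true selector differs (e.g. probability matching), $\alpha$
  estimates absorb the mismatch.
* `read_trials()` cannot recover switch points or generating
  probabilities from a log; analyses that need them (estimation windows,
  slope intervals) rely on the documented task constants.
* The mixed ANOVA covers one within and at most one between factor — the
  designs used here — not general factorial layouts.
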