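---
title: "Belief learning and strategy choice in repeated threshold public goods games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief learning and strategy choice in repeated threshold public goods games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggsl)
```

## The task and its dilemma

`pggsl` models behavior in a repeated *threshold public goods game*
(PGG). A group of `N = 5` members plays `T = 15` rounds with the same
partners. Each round every member receives an endowment of `E = 1`
monetary unit (MU) and privately decides to contribute it (cost
`c = 1` MU) or to keep it (free-ride). If at least `k` members
contribute, the public goods are produced and every member receives
`R = 2` MU. The per-round payoffs are therefore 2 MU for a contributor
and 3 MU for a free-rider when the goods are produced, and 0 MU versus
1 MU when they are not: free-riding dominates within a round by exactly
the contribution cost.

The threshold `k` (2 or 4 in the task, constant within a block) tunes a
*volunteer's dilemma*: a contribution is wasted both when too few
others contribute (the goods fail anyway) and when enough others
already contribute (the goods would have been produced regardless).
One's contribution matters only in the pivotal profile where exactly
`N - k` of the other `N - 1` members free-ride.

## The social learning model

The core model assumes that a player tracks a belief $\gamma_t$ — the
probability that any one other member will free-ride in round $t$ — and
converts it into two utilities:

* **Individual utility** $I_t$: the immediate expected gain of
  contributing relative to free-riding,
  $$I_t = \lambda + \Gamma_t^{N-k} R + \pi\, \Gamma_t^{N-k} R (N-1),$$
  where $\Gamma_t^i = \binom{N-1}{i}\gamma_t^i(1-\gamma_t)^{N-1-i}$ is
  the implied binomial belief over free-rider counts, $\lambda < 0$ is
  the subjective contribution cost and $\pi$ weighs the reward given to
  the other members (altruism). The closed form arises because the
  group reward differs between the two choices only in the pivotal
  profile $i = N - k$; `individual_utility_enum()` keeps the full
  profile sum as an independent oracle and the test suite verifies the
  identity to $10^{-10}$ over random draws.

* **Group utility** $G_t$: the cumulative expected group reward over
  the remaining rounds,
  $$G_t = \frac{1 - K^{T-t+1}}{1-K} \, R \sum_{i=0}^{N-k} \Gamma_t^i,
  \qquad K = k/N,$$
  which is large early in a block and shrinks as the horizon closes
  (`group_utility_sum()` is the term-by-term oracle; the $K = 1$ case
  uses the $(T-t+1)$ limit).

The decision value is the weighted sum $Q_t = \omega I_t +
(1-\omega) G_t$ with $\omega \in [0,1]$, and the contribution
probability is the logistic sigmoid of $Q_t$. We read the source
notation "logit" as the inverse-logit link throughout: a probability
must result, and the reported parameter scales only make sense under a
sigmoid.

After each outcome the belief is updated by a reinforcement rule driven
by the *social prediction error* $PE_S = F_{t-1}/(N-1) - \gamma_{t-1}$
(observed free-riding proportion minus belief) with learning rate
$f(\alpha + \theta\, PE_R)$, where the *reward prediction error*
$PE_R = |R \sum_{i=0}^{N-k}\Gamma_{t-1}^i - R_{t-1}|$ is the absolute
gap between the expected and realized group reward. We take $f$ to be
the standard logistic sigmoid: it guarantees a learning rate in
$(0,1)$ and hence a belief that remains a probability (the update is a
convex combination). A clipped-linear variant is available via
`rate_fn = "linear"` but is off by default. $R_{t-1}$ is the realized
group reward (0 or `R`), not the focal payoff. The belief is
initialized per subject as $\gamma_1 = 1 - $ `control_rate`, the
free-riding proportion the subject itself showed in non-feedback
control blocks, and resets at every block boundary because groups are
reshuffled.

Higher-order variants replace the belief entering the utilities with
its pivotal-profile transform ($\gamma^{1st} = \Gamma^{N-k}(\gamma)$,
applied once for order 2 and twice for order 3). The printed source
formula for the order-3 transform is typeset ambiguously; we implement
it as the same binomial mass evaluated at the order-2 belief, the only
reading symmetric with the order-2 definition. The learning update
itself always operates on the first-order belief — applying the
transform inside the update would break the convex-combination
guarantee.

## Competing models

Three alternatives are fitted with exactly the same session interface:

* **Myopic** ($\mu = 5$): $p(C_t) = \sigma(\omega I_t)$ with $\omega
  \ge 0$ unbounded above; beliefs update as in the social learning
  model.
* **Group utility / forward-looking** ($\mu = 4$): $p(C_t) =
  \sigma(\zeta + \chi G_t)$ with an initial bias $\zeta$.
* **Inequity aversion** ($\mu = 3$): $p(C_t) = p(C_1)\,\sigma\!\big(
  \kappa \sum_{i=1}^{t-1} [\varepsilon R_i - \delta (C_i - \bar C_i)]
  \big)$, where $\bar C_i$ is the others' contribution proportion and
  $p(C_1)$ is the control-block contribution rate taken from the data
  (not fitted). At $t = 1$ the probability is $p(C_1)$ itself; the
  accumulator starts with the first observed outcome. We read $\kappa$
  as multiplying the whole accumulated sum, consistent with its
  description as an inverse temperature.

All models enter the same Bernoulli likelihood over all `T` trials of
every block (trial 1 is driven by the initial belief or baseline; the
likelihood is not stated to exclude it), with probabilities clamped to
$[10^{-9}, 1-10^{-9}]$ — a pure numerical safeguard that never binds at
sensible parameters.

## Fitting, comparison, validation

`fit_mle()` minimizes the negative log-likelihood with bounded
`L-BFGS-B` from multiple starts: a small set of canonical starting
points per model followed by seeded random starts drawn from plausible
ranges narrower than the bound constraints (uniform starts over the
full $\pm 50$ boxes of the group-utility model routinely land on the
saturated shoulders of the likelihood where the gradient vanishes),
plus a final polish of the incumbent at the optimizer's default
tolerance. Twenty restarts is the default; fits are deterministic
given a seed. Bounds: $\omega \in [0,1]$ (social learning) or $[0,50]$
(myopic), $\pi \in [-5,5]$, $\lambda \in [-10,10]$, $\alpha \in
[-10,10]$, $\theta \in [-5,5]$, $\chi, \zeta \in [-50,50]$, $\delta \in
[0,50]$, $\varepsilon \in [-5,5]$, $\kappa \in (0,50]$.

Model comparison uses $\mathrm{BIC} = -2\ln\hat L + \mu \ln n$ per
subject (with $n$ the subject's trial count), summed across subjects,
plus random-effects Bayesian model selection on the subject-wise
evidences $-\mathrm{BIC}/2$: a variational Dirichlet posterior over
model frequencies and exceedance probabilities from $10^6$ posterior
draws. The protected variant is intentionally omitted; its
null-model comparison step is a separate construction and plain
exceedance probabilities answer the question asked here.
`loo_block_cv()` scores each block's predictive likelihood under
parameters fitted to the other blocks (blocks are independent given
the boundary resets), and `ablate_sl()` refits with one of $\alpha,
\theta, \lambda, \pi$ fixed at zero. Fixing $\alpha = 0$ leaves the
learning rate $f(\theta PE_R)$, matching the "rate with $\theta$ only"
reading and keeping the ablation a within-subject operation.

## The synthetic cohort generator

`simulate_cohort()` emulates the study layout: 25 subjects × 12 blocks
× 15 rounds, a balanced randomized schedule of `k = 2` and `k = 4`
blocks, per-subject generating parameters drawn from normal
distributions centred on the reported group means with spreads equal
to the reported SEMs scaled by $\sqrt{25}$ (i.e. the implied cohort
standard deviations), truncated to the fitting bounds, and control
rates drawn from a Beta(3, 2) distribution (mean 0.6 — a moderately
cooperative initial tendency, typical of such cohorts; the original
distribution is not published). One master seed drives a per-subject
seed sequence so cohorts are reproducible and stable under resizing.

The four co-players are computer agents with a logistic policy on the
previous round: they mirror the focal subject's control rate in round
1, then weigh their own previous decision (stickiness), their
co-members' previous contribution proportion, and a failure signal
that discourages contribution *in proportion to how uncooperative the
group already was*, scaled by the remaining horizon. The interaction
with uncooperativeness is deliberate: the documented agent behavior is
increased free-riding after failure *in a less cooperative group*, and
an unconditional failure penalty makes high-threshold groups spiral
into free-riding so that the documented cohort-level pattern (more
contribution under `k = 4` than `k = 2`) cannot emerge. The default
weights (intercept −2.8, stay 4.5, cooperativeness 2.2, failure −2,
horizon 1) were fixed by checking, across cohort seeds, that simulated
cohorts jointly show the documented phenomenology — sticky agents,
more contribution under the weaker dilemma, declining contribution
over rounds at both thresholds with the faster decay under `k = 4`.
They are declared defaults of this package, not estimates of the
original (unpublished) agent constants.

What the generator does *not* emulate: timed-out/repeated trials,
response times, any drift of motivation across blocks, and real human
co-players — agents follow one fixed policy family. Passing recovery
tests on these cohorts therefore demonstrates internal consistency of
the modelling pipeline under the stated conditions, not that the
models are identifiable on arbitrary human data.

## What recovery can and cannot show at the study scale

With 180 binary decisions per subject, the five social-learning
parameters are not equally identifiable. The decision weight $\omega$
and altruism $\pi$ recover well (the test suite requires the
generating–recovered correlation of $\omega$ to reach at least 0.5;
in practice it is substantially higher). The learning-rate pair
$(\alpha, \theta)$ enters the likelihood only through
$f(\alpha + \theta PE_R)$ with $PE_R \in [0, R]$ — a near-ridge that
180 trials barely constrain — and $\lambda$ trades off against $\pi$
through the affine structure of $I_t$. Consistency checks with many
more blocks per subject show the $\omega, \pi, \lambda$ biases vanish
with data while $(\alpha, \theta)$ remain hard; the acceptance suite
therefore reports group-mean recovery bias per parameter at the study
scale and is expected to flag the weakly identified ones. The
group-level directional test of $\theta > 0$ is demonstrated in the
unit tests on a cohort with 36 blocks per subject, where the
learning-rate information is sufficient.

Model recovery at the study scale has one structural caveat worth
knowing: under the reported myopic parameter scale ($\omega \approx
11$), most simulated subjects behave deterministically, every model
fits them perfectly, and BIC then ranks models purely by parameter
count — occasionally handing the cohort to the 4-parameter
group-utility model. This is a property of the comparison under those
generating conditions, not an optimizer artifact.

## Numerical choices

* Binomial masses and tails come from `dbinom()`/`pbinom()` (and their
  C counterparts in the compiled likelihood); the compiled path is
  asserted equal to the reference R implementation to $10^{-12}$.
* Probability clamp $10^{-9}$ in every likelihood.
* Geometric-sum limit $(T-t+1)$ for $K = 1$.
* The model-free analysis fits per-subject logistic regressions on 12
  lagged regressors (lags 1–3 of free-rider count, own decision,
  success, and the decision×success interaction; lags never cross
  block boundaries, so rounds 4–15 enter) and then one-sample t-tests
  across subjects. Separated subject fits (non-convergence or runaway
  coefficients) fall back to a ridge-penalized fit and are flagged.
* GLM confound orthogonalization projects confounds on the interest
  regressors plus an intercept (the canonical partialing; whether the
  original included an intercept is unstated) and is idempotent by
  construction.
* $\Delta Q$ at the first modeled outcome uses $Q_1$ computed under
  the initial belief, so every outcome event carries a defined value.

## Problem sizes used by the validation suite

The packaged tests run the full validation at deliberately chosen
sizes: parameter recovery on one 25 × 12 × 15 cohort with 20 restarts
per fit; model recovery with 20 replicates per generating model at 15
subjects each and 6 restarts per fit; calibration of the model-free
group test on 500 null cohorts of 15 subjects; oracle identities on
1000 random draws. `run_validate()` exposes the same analyses at
configurable (by default smaller) sizes for quick interactive use.
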