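---
title: "Belief volatility, metacognitive structure, and win-switch behavior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief volatility, metacognitive structure, and win-switch behavior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprl)
```

`metaprl` implements a complete belief-to-behavior analysis pipeline for
three-choice probabilistic reversal learning (PRL): a hierarchical Bayesian
learning model whose key individual-difference parameter is the *volatility
prior* $\mu_3^0$, a rubric-based scoring scheme for open-ended self-reflections
(*metacognitive prompting*, MP), and a moderation analysis asking whether
metacognitive structure attenuates how strongly volatility beliefs translate
into win-switch behavior. A synthetic-cohort generator makes every stage
runnable and testable without any external data.

## The task environment

The task is a three-option bandit with 160 trials. Reward probabilities start
at 0.9/0.5/0.1 and shift to 0.8/0.4/0.2 at trial 81 (each option keeps its
rank). Reversals exchange probabilities between options in two ways:
performance-independent reversals every 40 trials, and performance-dependent
reversals triggered when 9 of the last 10 choices selected the best option.

Where the verbal task description leaves mechanics open, the package fixes
them as explicit, configurable decisions:

* A reversal swaps the best and the worst option's probabilities, leaving the
  middle option unchanged (the simplest rule that changes the identity of the
  best option; `apply_reversal()` is exposed so other rules can be
  substituted).
* The performance window resets after *any* reversal, so a performance
  trigger can never fire within 10 trials of the previous reversal.
* If a scheduled reversal and a performance trigger coincide, one reversal is
  applied and labelled "scheduled".
* Trial indexing is 1-based; the trial-160 scheduled reversal is emitted but
  has no behavioral consequence.
* Outcomes are binary 0/1; a points mapping for display never enters any
  likelihood.

## The perceptual model

Beliefs are modelled with a three-level Hierarchical Gaussian Filter (HGF)
for binary outcomes in a multi-armed bandit: level 1 is the observed feedback
of the chosen option, level 2 the per-option reward tendency $x_{2,j}$ in
logit space, level 3 a single log-volatility state $x_3$ shared by all
options. Both latent levels carry AR(1) (mean-reverting) dynamics with rates
$\phi_2, \phi_3$ and attractors $m_2, m_3$.

Per trial, with posterior means $\mu_{2,j}, \mu_3$ and variances
$\sigma_2, \sigma_3$:

$$\hat x_{2,j} = \mu_{2,j} + \phi_2 (m_2 - \mu_{2,j}), \qquad
  \hat x_3 = \mu_3 + \phi_3 (m_3 - \mu_3)$$

$$v_2 = \exp(\kappa \hat x_3 + \omega), \qquad
  \hat\sigma_2 = \sigma_2 + v_2, \qquad
  \hat\sigma_3 = \sigma_3 + \vartheta, \qquad
  \hat m_j = s(\hat x_{2,j})$$

where $s(\cdot)$ is the logistic sigmoid. The chosen option $c$ is updated by
the precision-weighted binary prediction error $\delta_1 = y - \hat m_c$:

$$\pi_2 = \hat\sigma_2^{-1} + \hat m_c (1 - \hat m_c), \qquad
  \mu_{2,c} \leftarrow \hat x_{2,c} + \delta_1 / \pi_2, \qquad
  \sigma_2 \leftarrow \pi_2^{-1}$$

Level 3 is driven by the volatility prediction error
$\delta_2 = [\sigma_2 + (\mu_{2,c} - \hat x_{2,c})^2]/\hat\sigma_2 - 1$ with
weight $w_2 = v_2 / \hat\sigma_2$:

$$\pi_3 = \hat\sigma_3^{-1} + \tfrac{\kappa^2}{2} w_2
          \left[w_2 + (2 w_2 - 1)\delta_2\right], \qquad
  \mu_3 \leftarrow \hat x_3 + \tfrac{\kappa}{2}\tfrac{w_2}{\pi_3}\delta_2$$

**Shared level-2 variance.** Level-2 uncertainty is common to all options
(one scalar $\sigma_2$); only the means are option-specific, and unchosen
means merely drift toward $m_2$. This follows the multi-armed-bandit
convention for this model family and is also a numerical-stability decision:
with fully separate per-option variances, the variance of rarely chosen
options grows without bound, and the level-3 precision update $\pi_3$ can go
negative once the volatility prior is high. With the shared variance,
filtering is stable over $\mu_3^0 \in [-8, 3]$, well beyond the range any
analysis here uses. A remaining non-positive $\pi_3$ (possible under extreme
parameter settings) raises a typed instability error carrying the trial
index; during model fitting such evaluations are absorbed as a large penalty.

An independently coded, step-by-step reference implementation of these
equations lives in the test suite and pins the filter to $10^{-10}$.
Cross-checking against the publicly released configuration of the original
MATLAB toolbox is a documented validation step for users with access to it,
not a code dependency.

## The response model

Choices follow a volatility-dependent softmax on the predicted outcome
probabilities with inverse temperature $\beta = \exp(-\hat x_3)$: decision
noise grows with currently inferred volatility. The *prediction* $\hat x_3$
(pre-outcome) is used, so a choice never conditions on the outcome it
produces. The sign convention (noise increasing with volatility) is the
substantive hypothesis of the model — an agent convinced the world is
changing has little reason to exploit — and is the package's fixed choice.

## Parameters, priors, and fitting

MAP inversion maximizes choice log-likelihood plus Gaussian log-priors over
the *free* parameters in an unbounded estimation space (log for
variance-like parameters, logit for AR(1) rates). A parameter is free iff its
prior variance is positive; priors live in a YAML file
(`inst/extdata/hgf_priors.yaml`) mirroring the structure prior-mean /
prior-variance per parameter, and can be replaced wholesale. The shipped
defaults make the volatility prior $\mu_3^0 \sim N(-3, 4)$ the single free
parameter and fix $\kappa = 0.2$, $\omega = -0.5$, $\vartheta = 0.5$,
$\sigma_2^0 = 0.5$, $\sigma_3^0 = 1$, $\phi_2 = 0$, $\phi_3 = 0.02$,
$m_2 = 0$, $m_3 = -3$.

This operating point was chosen once, from forward simulation of the model
against the task, by three criteria:

1. *Stability*: no filtering instabilities across $\mu_3^0 \in [-8, 3]$.
2. *Responsiveness*: the session-level win-switch rate rises monotonically
   with $\mu_3^0$ (from ~0.005 at $\mu_3^0 = -6$ to ~0.22 at $+1$), and
   approximately linearly on the logit scale over $[-5, -1]$ — the region the
   synthetic cohort occupies.
3. *Interpretability*: with small $\kappa$, the volatility prior acts mainly
   through decision noise rather than through the learning rate, so "higher
   volatility expectation leads to more erratic switching" is the dominant causal
   channel.

The optimizer is BFGS with jittered restarts (first start at the prior mean,
the rest drawn from the prior; best log-joint wins, ties to the first found).
With one free parameter, recovery is strong: fit-refit correlations around
0.9 at 40 participants.

## Model-free behavior

The win-switch rate (WSR) is the proportion of rewarded trials followed by a
different choice, out of all rewarded trials. The final trial is excluded
from the denominator (it has no successor); with no rewarded trials the rate
is flagged missing rather than raising an error. Lose-stay and other
model-free metrics are deliberately omitted.

## Metacognition scoring

Reflections (the concatenated answers to two open-ended debrief prompts) are
scored on five dimensions — Comprehension, Judgement, Evaluation, Final
Decision, Confidence — each as a probability distribution over rubric levels
0–4. The continuous dimension score is the expected value
$M_d = \sum_i P_i \, i$, and the overall index $\bar M$ is the mean of the
five. Reflections with fewer than 10 non-whitespace characters (configurable)
bypass the backend entirely and score a point mass at level 0.

Scoring backends are pluggable functions `text -> five probability vectors`.
Two ship with the package:

* `mp_backend_mock()` — a deterministic rule-based scorer mapping transparent
  text features (task vocabulary, pattern/conditional markers, evaluative
  phrases, rule statements, confidence phrases, and a mild saturating length
  credit) to the five distributions. Each raw score is monotone
  non-decreasing in its features, and the returned distribution splits mass
  between adjacent levels so its expected value equals the raw score exactly.
  All tests use this backend.
* `mp_backend_llm()` — an adapter that builds the structured scoring prompt
  and delegates the completion to a user-supplied function (e.g. a
  temperature-0 chat API call), parsing a JSON reply. The package performs no
  network access itself; reproducing any particular LLM's scores is out of
  scope.

Covariates: verbosity is the character count of the combined reflection; the
general-cognition composite is the *literal* average of the 1–8 education
level and 0–1 CRT accuracy. The two scales are mixed deliberately —
the composite is z-scored before entering any model, so only its ordering
matters. CRT answers are scored by a normalization that accepts numeric,
number-word, currency and unit variants. Rater reliability uses two-way
random-effects absolute-agreement ICCs, computed from ANOVA mean squares
(there is no ICC package dependency).

## Moderation analysis

Win-switch behavior is modelled as binomial counts (switches out of win
trials) in a logit-link GLM:

$$\mathrm{WSR} \sim \beta_0 + \beta_1 z(\mu_3^0) + \beta_2 z(\bar M)
  + \beta_3\, z(\mu_3^0) \cdot z(\bar M) + \beta_4 z(V) + \beta_5 z(C)$$

Counts (rather than a quasi-binomial proportion) weight participants by their
available win trials; participants with zero win trials are excluded and
reported. All regressors are z-scored once on the analysed sample. The
interaction is tested by a likelihood-ratio test against the nested model;
main effects are reported as odds ratios with Wald CIs and as average
marginal effects $\overline{\beta\, p (1 - p)}$ on the probability scale.

Because bounded outcomes bend near 0, a null interaction on the link scale
still produces different probability-scale rises at different MP levels, and
conversely a real attenuation may be invisible to the global LRT. The
probability-scale contrast therefore evaluates the predicted rise in WSR as
$z(\mu_3^0)$ goes from $-1$ to $+1$ SD, at $z(\bar M) = \pm 1$ SD (controls
at 0), and reports `delta = pp_high - pp_low` with a percentile 95% CI from a
nonparametric bootstrap (participant resampling, 1,000 iterations by
default, z-score columns held fixed, `glm` refit per resample; more than 5%
failed refits is an error). A Breusch–Pagan test (LM and companion F form)
documents the mean–variance coupling that motivates the GLM over OLS, and a
covariates-only model (verbosity + cognition) is fitted as the control
comparison.

Group comparisons use Welch t-tests with pooled-SD Cohen's d, or Welch
one-way ANOVA beyond two levels.

## Simulation experiments

**Parameter recovery** treats per-participant parameters as ground truth,
simulates full closed-loop sessions (all reversal and shift logic active), 3
repetitions per participant by default, refits each simulated session with
identical priors, and correlates recovered with true values across
participants (failed refits are recorded and excluded).

**The volatility-prior grid experiment** holds each participant's parameters
fixed, sweeps only $\mu_3^0$ over a 15-point grid spanning the 15th–85th
percentiles of the empirical $\mu_3^0$ distribution (linear interpolation
between order statistics), simulates 100 sessions per participant and grid
value, and averages WSR into subject-level curves. Curves are averaged into a
population curve and into low/high-MP group curves (split at $\pm 1$ SD of
z-scored $\bar M$; mid-MP participants are discarded and retained group sizes
are reported). The interaction test regresses the two *group-mean* curves (15
points each) on grid value with a group indicator — participant-level
clustering is deliberately ignored to match the group-curve procedure.

## The synthetic cohort

`generate_cohort()` emulates a cohort of 486 online participants with a
high-paranoia subgroup of 99 (persecution-score cutoff 11): group-linked
elevation of the volatility prior (target d = 0.63), group-linked reduction
in reflective structure (target d = 0.73) and reflection length, and trial
data generated by HGF agents playing the task. Persecution scores are drawn
from a zero-inflated discrete distribution consistent with the cutoff;
demographics are generated but carry no effects.

Two properties deserve emphasis:

* **The win-switch gap is emergent.** Only the volatility prior differs by
  group; the WSR difference (d around 0.5–1.0 at n = 200) arises entirely
  through the agent-environment loop, preserving the causal chain from belief
  to behavior.
* **Metacognitive buffering is encoded generatively.** The volatility prior
  each agent *acts on* is its drawn prior compressed toward the population
  mean in proportion to `mp_gating * level/4` (default 0.6), plus a small
  direct dampening per structure level (`mp_direct`, default 0.25) that
  encodes the negative main effect of reflection on switching. Reflection
  texts are built from structure-level templates with independent neutral
  filler sentences, so verbosity correlates with structure (~0.85) without
  being a deterministic proxy — under perfect collinearity the verbosity
  control would absorb the metacognition effect entirely.

What the generator does *not* emulate: real free-text diversity (templates
with limited variation), item-level paranoia-scale structure, demographic
effects, and the empirical negative WSR–performance correlation at the
default operating point. On the last point: in this model family extra
decision noise also speeds post-reversal adaptation, so the model-implied
WSR–performance relation is flat near the default cohort centre and turns
negative only above $\mu_3^0 \approx -1$ (where switching is genuinely
maladaptive). The empirical strongly negative correlation in human data is
driven by extreme near-random responders that the default cohort deliberately
does not contain; the property is demonstrated in the maladaptive regime
instead. Passing tests therefore certify the pipeline's statistical
machinery and the encoded qualitative structure, not distributional realism
of human reflections or behavior.

## Numerical choices and problem sizes

* Percentiles: linear interpolation between order statistics (type 7).
* Bootstrap and null-calibration checks in the test suite run at reduced but
  statistically meaningful sizes chosen as the package's own test design:
  cohorts of 120–200 participants, 200–400 bootstrap iterations, 100–500
  simulation replicates; the grid experiment runs at 40 participants with
  the full 15-point/100-repetition protocol.
* One global seed fans out to every stochastic stage through
  `derive_seed(seed, stage, k)`, so stages re-run independently yet
  reproducibly; all seeds stay below $2^{31}$.
* Optimizer restarts default to 10 for single fits; the recovery experiment
  uses 3 restarts per refit (one free parameter).

## Known limitations

* The shipped priors are package defaults, not the original study's
  supplementary values; users reproducing that study should replace the YAML
  with the published table.
* Which parameters were free in the original inversion is unknown; the
  default frees only $\mu_3^0$.
* The mock scorer is transparent and monotone by construction; it is a test
  instrument, not a model of LLM scoring.
* The group-curve interaction test inherits the original procedure's
  limitation of ignoring subject-level clustering.

## A worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_total = 200, n_high_paranoia = 41, seed = 11)
out <- run_pipeline(spec, n_boot = 500)
print(out$results)
plot_moderation(out$results)
```
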