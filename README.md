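# metaprl

Does self-reflection keep volatile beliefs from becoming erratic behavior?
`metaprl` is an R package for studying that question in three-choice
probabilistic reversal learning (PRL): it simulates and fits a three-level
mean-reverting Hierarchical Gaussian Filter (HGF) whose key
individual-difference parameter is the volatility prior μ₃⁰, scores
open-ended task reflections on a five-dimension metacognitive rubric
(comprehension, judgement, evaluation, final decision, confidence), and tests
whether metacognitive structure attenuates the link between volatility
beliefs and win-switch behavior.

The pipeline mirrors a complete computational-psychiatry analysis:

* **Task environment** — 160-trial, three-option bandit; 0.9/0.5/0.1
  probabilities shifting to 0.8/0.4/0.2 at trial 81; scheduled reversals
  every 40 trials and performance-triggered reversals after 9-of-10 best
  choices (`task_config()`, `run_session()`).
* **Perceptual + response model** — binary multi-armed-bandit HGF with AR(1)
  dynamics; level 3 tracks log-volatility; choices follow a
  volatility-dependent softmax with inverse temperature β = exp(−x̂₃).
  Filtering (`filter_beliefs()`), closed-loop simulation
  (`simulate_agent()`), and MAP fitting with YAML-configured priors
  (`fit_map()`, `hgf_priors()`).
* **Behavior** — win-switch rate and reward rate (`win_switch_rate()`).
* **Metacognition** — expected-value scores `M_d = Σ P_i·i` over rubric
  levels 0–4 from a pluggable scorer backend (deterministic rule-based mock
  shipped; LLM adapter contract provided), verbosity and a
  general-cognition composite, CRT answer normalization, and ICC(2,1)/
  ICC(2,k) rater reliability.
* **Inference** — binomial GLM `WSR ~ z(μ₃⁰) * z(M̄) + z(V) + z(C)` on
  switch/win-trial counts, likelihood-ratio tests, odds ratios, average
  marginal effects, ±1 SD predicted probabilities, 1,000-iteration bootstrap
  probability-scale contrasts, Breusch–Pagan diagnostics, and Welch group
  comparisons (`fit_moderation()`, `bootstrap_contrast()`,
  `analyze_table()`).
* **Experiments** — parameter recovery (simulate-from-fit, refit, correlate)
  and the μ₃⁰-grid experiment mapping the volatility prior onto expected
  win-switch rate, split by metacognition group (`parameter_recovery()`,
  `belief_behavior_mapping()`).
* **Synthetic cohort** — a generator emulating a 486-participant online
  cohort with a 99-participant high-paranoia subgroup (elevated μ₃⁰, lower
  reflective structure, shorter reflections), whose win-switch gap emerges
  through the agent-environment loop rather than being injected
  (`cohort_spec()`, `generate_cohort()`, `run_pipeline()`).

See `vignettes/methods.Rmd` for the models, update equations, parameter
defaults, and design decisions.

## A worked example

```r
library(metaprl)

spec <- cohort_spec(n_total = 200, n_high_paranoia = 41, seed = 11)
out  <- run_pipeline(spec, n_boot = 500)
print(out$results)
```

```
Participants analysed: 200
group WSR:   t = 3.04, p = 0.00358, d = 0.58
group mu3_0: t = 3.68, p = 0.000461, d = 0.61
group M_bar: t = -2.40, p = 0.0198, d = 0.48
cor(WSR, performance) = 0.04
OR[z(mu3_0)] = 2.48 [2.23, 2.75]; OR[z(MP)] = 0.91 [0.74, 1.12]
AME[z(mu3_0)] = +0.022; AME[z(MP)] = -0.002
LRT interaction: X2(1) = 13.21, p = 0.000278
pp rise (-1 -> +1 SD mu3_0): low MP +5.0 pp, high MP +2.3 pp
delta = -2.7 pp, bootstrap 95% CI [-5.1, -0.7] (500 iters)
```

Reading the output: the synthetic high-paranoia group holds higher volatility
priors (d = 0.61, injected by the generator) and win-switches more (d =
0.58, *emergent* through the HGF agents), while scoring lower on
metacognitive structure (d = 0.48). In the moderation model, a +1 SD higher
volatility prior more than doubles the odds of switching after a win (OR =
2.48), and the probability-scale contrast shows the buffering effect the
generator encodes: moving the volatility prior from −1 to +1 SD raises
predicted win-switching by 5.0 percentage points at low metacognition but
only 2.3 at high metacognition (delta = −2.7 pp, CI excluding 0).

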