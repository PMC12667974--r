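---
title: "Modeling Pavlovian bias on the orthogonalized go/no-go task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Pavlovian bias on the orthogonalized go/no-go task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gngbias)
```

## The task and the model

The orthogonalized go/no-go task crosses required action (go / no-go) with
cue valence (win / avoid-losing), giving four conditions presented in
randomized order (default: 45 trials each, 180 total). Feedback is
probabilistic: the optimal outcome follows a correct response with
probability 0.8 and an incorrect one with probability 0.2. Win cues
deliver outcomes in $\{+1, 0\}$, avoid cues in $\{0, -1\}$. Both schedule
probabilities are explicit fields of `task_design()`, so the asymmetric
reading of the contingency (only the incorrect-response probability stated,
correct-response probability different from 0.8) can be configured if a
variant of the task calls for it.

The agent is a Rescorla–Wagner learner with Pavlovian modulation. Action
values $Q(a, s)$ and action-independent state values $V(s)$ both start at
zero and move a fraction $\varepsilon$ toward $\rho\, r_t$ after each
outcome, with $\rho = \rho_{rew}$ on win cues and $\rho_{pun}$ on avoid
cues. The go action weight adds a constant go bias $b$ and a Pavlovian
term $\pi_v V(s)$ ($\pi_{rew}$ on win cues, $\pi_{pun}$ on avoid cues);
choices follow a softmax mixed with a lapse rate $\xi$ toward 0.5. Because
$V(s)$ becomes positive under reward learning and negative under
punishment learning, positive $\pi$ invigorates go for win cues and
suppresses it for avoid cues — which produces the familiar behavioral
signature: congruent conditions (go-to-win, no-go-to-avoid) are learned
better than incongruent ones.

Parameter conventions (7 per session): $\varepsilon, \xi \in (0,1)$ via
the probit transform of unconstrained values; $\rho_{rew}, \rho_{pun} > 0$
via the exponential; $b, \pi_{rew}, \pi_{pun}$ unbounded. The positivity
constraint on $\rho$ is a modeling choice — it keeps "sensitivity"
interpretable and follows the model family this task is analyzed with;
only the probit-bounded parameters are forced by the model definition.

Two choices deserve note because the model description leaves them open.
First, the two-session design adds seven delta parameters, and we add
deltas **in the unconstrained space before** the constraints
(`session2_parameters()`): this guarantees bounded parameters stay in
range for any delta, which an addition in the natural space would not.
Second, $V(s)$ updates on every trial regardless of the action taken; the
state value tracks the cue's outcome history, not the chosen action's.
With $r = 0$ the $\rho$ term vanishes, so the valence-of-cue vs
sign-of-outcome ambiguity in "reward vs punishment sensitivity" never
materializes: win cues only ever deliver $\{+1, 0\}$ and avoid cues
$\{0, -1\}$.

The likelihood accumulates in log space and the softmax subtracts the max
weight before exponentiation; choice probabilities are floored at 1e-300
before the log.

## Hierarchical estimation without gradients

Subject-level unconstrained parameters are modeled non-centered:
$\eta_{ik} = \mu_{g(i),k} + x_i^\top \beta_k + \sigma_k z_{ik}$ with
$z_{ik} \sim N(0,1)$, $\mu, \beta \sim N(0,1)$ and
$\sigma_k \sim \text{half-}N(1)$. The prior scales are weakly informative
on the unconstrained scale, where all parameters live in roughly
single-digit ranges. Group-specific means (e.g. quitters vs non-quitters)
share the $\sigma_k$; fitting both groups jointly gives the group
contrasts a joint posterior, and separate fits remain possible by
subsetting the trial table.

The sampler (`fit_hierarchical()`) is an adaptive Metropolis-within-Gibbs
scheme written in C++:

- componentwise Gaussian random-walk updates for every $z_{ik}$,
  $\mu_{gk}$, $\beta_{ck}$ and $\log \sigma_k$ (half-normal prior plus
  log-scale Jacobian), with per-parameter step sizes adapted toward a 0.44
  acceptance rate during warmup (Robbins–Monro, decay $t^{-0.6}$) and
  frozen afterwards;
- two *interweaving* moves that exploit the non-centered structure: a
  translation that shifts $\mu_{gk}$ and counter-shifts the group's
  $z_{ik}$ so every $\eta_{ik}$ (hence the likelihood) is unchanged, and a
  rescaling of $(\sigma_k, z_{\cdot k})$ with the same property. These
  moves cost no likelihood evaluations and decorrelate the group-level
  parameters from the subject deviations, which is where plain
  componentwise Metropolis mixes worst.

Each stored iteration performs `thin` full sweeps (default 16); caching of
per-subject session log-likelihoods means a sweep costs
$O(N \cdot \text{trials})$ likelihood work. Chains are initialized with a
modest random spread (`init_jitter = 0.3`) so the split R-hat diagnostic
retains power to detect non-convergence without starting chains in
regions the posterior never visits.

Diagnostics use the classic split-half Gelman–Rubin statistic (no rank
normalization), with 1.1 as the working convergence bound, and an
initial-positive-sequence effective-sample-size estimator. Posterior
intervals are highest-density intervals computed exactly on sorted draws
(narrowest window containing $\lceil \text{mass} \cdot n \rceil$ draws,
earliest window on ties); constant draw vectors give zero-width intervals
and zero-variance chains flag R-hat as undefined rather than returning a
number.

`map_estimate()` offers a deterministic per-subject alternative
(penalized ML, standard-normal penalty by default) used for fast checks
and as the no-pooling reference when demonstrating shrinkage. With a unit
penalty the MAP itself shrinks toward zero, so shrinkage comparisons
against the hierarchical posterior use a near-flat penalty
(`penalty_sd = 10`), i.e. effectively per-subject maximum likelihood.

## Behavioral and cohort statistics

`congruency_contrasts()` reports the two within-subject contrasts
(go-to-win vs no-go-to-win; no-go-to-avoid vs go-to-avoid) with paired t
tests computed from first principles and the **average-variance pooled-SD
Cohen's d**, $d = (m_1 - m_2)/\sqrt{(s_1^2 + s_2^2)/2}$. The pooled form
(rather than the difference-score SD) is the only standard formula
consistent with published (mean, SD, d) triples for this task family, and
the package's tests pin it against four such triples. P-values are
two-sided and uncorrected, matching how these contrasts are convention-
ally reported.

Cohort QC (`apply_exclusions()`) excludes, in priority order: raised
data-issue and low-concentration flags, go responses on more than 90% of a
session's trials, any parameter split R-hat above 1.1, and fewer than 7
completed survey days; each excluded subject gets exactly one reason code
(first match), so retained + excluded always partitions the cohort.
Abstinence is CO-verified with a strict threshold (CO < 5 ppm *and* no
reported smoking in the last week).

The moderation analysis (`fit_quit_model()`) is a plain maximum-likelihood
logistic regression of quit outcome on smoking duration, sex (female as
reference), BIS, KTSND, CWS, YBOCS, clinic participation rate, the
subject-level reward Pavlovian bias, and optionally the
participation × bias interaction. All continuous predictors are z-scored
before entry and the interaction is formed from the standardized
components — coefficient magnitudes near 1 for a rate bounded in [0,1]
are only interpretable this way — and the package's tests confirm the fit
is invariant to rescaling any continuous covariate. The subject-level
bias covariate defaults to the posterior mean of the natural-scale
session-1 $\pi_{rew}$ (the median is one line of code away since the full
draws are exposed). `moderation_profile()` turns the interaction into
simple slopes $\beta_{part} + \beta_{int}\pi$ with delta-method SEs.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the statistical structure the analysis
assumes: subject parameters from group-level normals (defaults chosen to
produce condition accuracies in the 0.6–0.85 band with congruent >
incongruent, i.e. learning rate ≈ 0.2, sensitivities ≈ 4, go bias 0.2,
Pavlovian biases 0.6/0.5, lapse ≈ 0.15); a session-2 reward-bias shift of
+0.8 (unconstrained scale) for quitters only; independent standard-normal
survey covariates; Beta(6, 2) participation rates; CO readings on the
correct side of 5 ppm for each group (quitters uniform(0, 5),
non-quitters uniform(5, 30), so the abstinence classifier is exercised on
both sides); and a quit-outcome logistic model whose default coefficients
mirror the reported moderation structure. Two outcome modes reconcile
fixed group sizes with the generative quit model: `"group"` fixes
n_quit/n_nonquit labels (used when studying group-level deltas at known
group sizes), `"logistic"` draws quit from the logistic model and lets
the realized outcome select each subject's delta group (used when
studying the moderation model itself).

Deliberately *not* emulated: covariate correlations (unknown for real
cohorts), dropout and daily-survey time series, reaction times, session
timing, and any physiological detail of shock delivery. Passing recovery
tests on these cohorts therefore shows the estimation machinery is
correct and well calibrated under the model's own assumptions — it does
not certify robustness to model misspecification in real data.

## Problem sizes and numerical settings

The package's reference configurations, used throughout its tests: a
15-subject cohort at 2 chains × 600 iterations (300 warmup) for
convergence checks (max split R-hat ≈ 1.03–1.05 across seeds); a
50-subject, two-session cohort for parameter recovery (subject-level
$\pi_{rew}$ truth–estimate correlation ≈ 0.8, group-level quitter
$\Delta\pi_{rew}$ credibly positive); ten 20-subject replicates at
lighter settings (2 × 400, thin 4) for delta-sign recovery; and 20
replicates of n = 500 cohorts for logistic-interaction recovery. The
paper-scale sampler configuration (4 chains × 4000, 2000 warmup) is the
function default for real analyses.

Known limitations: the random-walk sampler needs many sweeps where
Hamiltonian methods would need few iterations — the `thin` default trades
wall-clock time for effective samples, and very large cohorts will be
slow; weakly identified parameters (notably $\rho_{rew}$ and its delta)
recover with attenuated correlation and below-nominal per-subject
interval coverage at 180 trials per session, a property of the model and
data size rather than the sampler; and the covariate design applies the
same linear effect to all 14 group means rather than a selected subset.
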