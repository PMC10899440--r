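---
title: "Modelling instrumental learning with mixed reinforcement-learning and working-memory systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling instrumental learning with mixed reinforcement-learning and working-memory systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlwm)
```

## The model

In stimulus–action association tasks, people learn which of a few
response keys is rewarded for each stimulus. Two systems contribute to
this learning. A slow reinforcement-learning (RL) system updates the
value of the chosen action by the delta rule,

$$Q_{RL}(s_t, a_t) \leftarrow Q_{RL}(s_t, a_t) + \alpha\,(r_t - Q_{RL}(s_t, a_t)),$$

with learning rate $\alpha$ driven by the reward prediction error
$r_t - Q_{RL}$. A fast working-memory (WM) system stores the last
outcome for a stimulus–action pair exactly (learning rate 1) but holds
only about $K$ items and decays toward the uninformative initial value
$Q_0 = 1/n_A$ (three actions, so $1/3$) on every trial:

$$Q_{WM} \leftarrow Q_{WM} + \varphi\,(Q_0 - Q_{WM}).$$

Each system turns its values into a softmax policy with shared inverse
temperature $\beta$, and the choice policy is their mixture, weighted by
the capacity-scaled WM reliance

$$P_{WM} = \rho \cdot \min(1, K/n_s),$$

where $n_s$ is the number of distinct stimuli in the block (the set
size) and $\rho$ the WM prior weight. Finally undirected decision noise
$\varepsilon$ blends the mixture with the uniform policy:
$\pi' = (1-\varepsilon)\pi + \varepsilon/3$. Accuracy in small set
sizes is therefore dominated by the fast WM system while large set
sizes expose the slow RL system — the signature the task is designed to
elicit.

`rlwm_params()` holds the six parameters ($\alpha, \varphi, \rho,
\varepsilon, \beta, K$); the step primitives (`wm_weight()`,
`softmax_policy()`, `mix_and_noise()`, `rl_update()`, `wm_store()`,
`wm_decay_step()`) expose each piece, and a compiled loop with the same
semantics powers simulation and likelihood evaluation at scale. The
unit tests verify the two paths agree to within $10^{-12}$.

### Update-order conventions

Several timing details are not pinned down by the model equations
themselves; the package fixes them as follows and applies them
identically in simulation and fitting:

* feedback updates run in the order RL update, WM one-shot storage,
  then WM decay of **all** stored entries (post-feedback decay is the
  common convention for this model family);
* both Q tables reset to $Q_0$ at every block start, because each block
  introduces new stimuli; there is no cross-block transfer;
* noise is applied once to the mixed policy, not to the subsystem
  policies;
* reward is deterministic: 1 for the correct key, 0 otherwise;
* timeout (invalid) trials trigger neither updates nor likelihood
  contributions.

## The task

The default session (`task_config()`) is a training block (set size 3,
12 presentations, excluded from all analyses) followed by ten learning
blocks with set sizes 2–5 and 12–14 presentations per stimulus,
totalling 468 trials. The published task fixes only the totals, not the
per-block composition; the default composition (set sizes
2,3,4,5,2,3,4,5,3,4 with presentation counts 12,12,13,12,12,12,12,13,13,12)
is one feasible instantiation and is fully overridable. Stimulus
sequences are pseudo-randomly interleaved by seeded shuffling with
rejection until no stimulus repeats more than `max_run_length` (default
3) times consecutively; a clearly infeasible constraint raises an
error rather than looping.

## Maximum-likelihood fitting

`rlwm_fit()` replays a subject's realized choices through the agent
state and minimizes the negative log-likelihood with L-BFGS-B from
multiple seeded random starts inside the bounds $\alpha, \varphi, \rho,
\varepsilon \in [0,1]$, $\beta \in [0.1, 50]$; the discrete capacity
$K$ is scanned exhaustively over $\{2,3,4,5\}$. Start points are drawn
uniformly (log-uniformly for $\beta$), ties broken by first-found, and
the whole procedure is a pure function of (data, settings, seed).
Because the uniform policy is nested at $\varepsilon = 1$, any fit with
free $\varepsilon$ satisfies $\mathrm{NLL} \le T\ln 3$; the per-trial
probability is floored at $10^{-12}$ inside the logarithm only, to
guard fits at $\varepsilon = 0$. By default $\beta$ is fitted and $K$
scanned, but analyses downstream use the four parameters the behavioral
literature interprets ($\alpha$, $\varphi$, $\rho$, $\varepsilon$), and
the recovery harness fixes $\beta$ and $K$ at their generating values.

### What parameter recovery can and cannot show

`parameter_recovery()` simulates subjects at known parameters, refits,
and reports per-parameter correlation, bias and RMSE. Two structural
facts limit recovery under *uniform* parameter draws across the full
unit cube: draws with large $\varepsilon$ carry almost no information
about the learning parameters, and when $\rho$ is high the WM system
dominates choices so the RL rate $\alpha$ only acts through the small
$(1-P_{WM})$ share. Recovery is therefore excellent for $\varepsilon$,
good for $\varphi$ under realistic ranges, and modest for $\alpha$ and
$\rho$; the recovery report makes these limits measurable instead of
hiding them (the fitted likelihood is verified to be at least as good
as the generating parameters' likelihood on every subject, so the
limitation is informational, not an optimizer artifact). More data
helps: the test suite checks that recovery on two-block sessions is
strictly worse than on the full ten-block session.

## Learning curves and logistic growth

`compute_learning_curves()` aligns trials on the presentation index
(iteration) of each stimulus and averages correctness, per set size or
pooled, truncating every curve at the minimum per-stimulus presentation
count so all cells are balanced. `fit_logistic_growth()` fits

$$P(t) = \frac{A}{1 + B e^{-kt}}$$

by bounded least squares ($A \in (0,1]$, $B \in (0,10^3]$, $k \in
(0,10]$) with a deterministic initialization rule ($A_0$ at the curve
maximum, $k_0$ on a small fixed grid, $B_0$ solved from the first
point), so the fit is a pure function of the data; it is exact to
$10^{-4}$ relative error on noiseless in-class curves. Curves with no
measurable rise are flagged `degenerate` with $k$ reported at its lower
bound rather than mis-fit.

The learning-initiation index is the first iteration at which the
fitted curve has risen a given fraction (default 10%) of the way from
its first-iteration value to the asymptote. Read literally, a "10% of
the maximum" threshold is already exceeded at the first iteration for
any above-chance curve, which contradicts the intended late initiation
indices; the baseline-normalized rise is therefore the default and the
literal rule remains available via `rule = "literal"`.

The rate-ratio comparison (`ratio_identity()`) contrasts
$(\bar\alpha_1/\bar\alpha_2)/(\bar\varphi_1/\bar\varphi_2)$ with
$(\tau_1/\tau_2)(RT_1/RT_2)$ for two groups. The package computes and
reports both sides with their relative gap; equality is an empirical
observation about a particular cohort, not a law, so it is never
asserted.

## The synthetic cohort generator

No subject-level data are deposited for the study this package is
built around, so `generate_cohort()` creates complete synthetic
cohorts. The default emulates a 48-subject cross-sectional design: 22
young adults (ages 25–40), 11 cognitively normal middle-aged adults and
15 middle-aged adults with MCI-range screening scores (ages 41–65;
MoCA ≥ 26 normal, 18–25 MCI, sampled uniformly with no attempt at MoCA
psychometrics).

Parameters are truncated-normal draws in $[0,1]$ with common SD 0.15.
The group separations encode the reported standardized effects: young
vs normal middle-aged $d = +0.56$ for $\alpha$, $-0.54$ for $\varphi$,
$-0.44$ for $\varepsilon$ and $0$ for $\rho$; normal vs MCI middle-aged
$-0.53$ for $\varepsilon$ only. Because truncation shifts moments, the
underlying normal locations were calibrated analytically so the
*realized* (post-truncation) effect sizes equal those targets; the
calibrated locations are frozen constants. Within-group SDs are free
generator constants (no published values exist) and are echoed into the
cohort provenance file. Within the middle-aged groups, the $\varphi$
and $\varepsilon$ locations drift by small per-year slopes (0.004 and
0.003 per year) centered on the mid-range age, so monotone
age–parameter trends are exercisable without changing group means. All
subjects share $\beta = 8$ and $K = 3$.

Reaction times are generated at the subject level — the model itself
has no RT likelihood, and no diffusion model is attempted — as
$\mathrm{RT} = b_0 + b_\varphi \varphi + b_\rho \rho$ plus per-trial
Gaussian noise and an increment on error trials, clipped to the 7 s
response window. The decay and prior coefficients are the reported
regression values (young: 722.22 and 137.07 ms per unit; middle-aged:
2355.98 and 156.34), while intercepts (600/550/800 ms), noise SD
(150 ms) and the error increment (120 ms) are free constants chosen to
give plausible overall RTs and a positive error-minus-correct gap.

What the generator deliberately does **not** emulate: real subjects'
strategy shifts and non-stationarity, RT dynamics within a block,
dropout demographics beyond the accuracy filter, and any MoCA
psychometrics. Tests that pass on this cohort therefore certify the
pipeline's statistical machinery and the model's internal consistency,
not fidelity to any specific human dataset.

## The statistical battery

`compare_groups()` follows the normality-gated convention: Shapiro–Wilk
on each group, Mann–Whitney U if either deviates at $p < 0.05$, else
Welch's t; Cohen's d is always reported and Bonferroni adjustment is
explicit — each analysis table declares its own family (the four model
parameters form one family, so `family_size = 4`) and the family size
is logged next to every adjusted value. Age trends report Spearman's
$\rho$ and the linear-regression $r^2$ side by side because the two can
disagree; parameter correlation tables report the coefficient matrix
and the p-value matrix separately. The exclusion rule removes subjects
with overall accuracy strictly below 33%; exactly 33% is kept. The
logistic age classifier regresses an over-cutoff indicator on the
per-set-size RTs and accuracies over cutoffs 35–44 with a seeded
stratified 75/25 split (the published split fraction is unstated);
cutoffs that leave a class empty are skipped and flagged. RT summaries
use valid trials only, pooling correct and error trials.

## Problem sizes and determinism

Every stochastic function takes a seed and restores the caller's RNG
state; cohorts, fits and pipeline report bundles are byte-identical
under identical configuration and seed, which the acceptance tests
check via content hashes. The heavier validation experiments run at
study scale chosen for a laptop-class budget: the likelihood/simulation
consistency check uses 10,000 agents on a two-block session; the
set-size effect is measured as late-learning accuracy, defined as the
second half of the guaranteed presentation range (iterations 7–12),
over 500 WM-limited agents; parameter recovery uses 100 subjects on the
full session; the group-pattern
replication uses 20 cohorts of 100 subjects per group fitted with 2
optimizer starts and $\beta, K$ fixed; `scripts/acceptance.R` re-runs
scaled-down versions (40 recovery subjects, 5 pattern replicates of 60
per group) of the same computations.

## Known limitations

* $\alpha$ and $\rho$ are weakly identified whenever WM dominates
  choice; group differences in *fitted* $\alpha$ are noisier than the
  generating differences, and significance patterns on fitted
  parameters at the configured effect sizes replicate less often than
  the same patterns on the generating values.
* The logistic growth model has no lapse floor, so curves that start
  above their asymptote (possible in tiny samples) fit degenerately.
* The RT generator is linear and subject-level; it cannot produce
  speed–accuracy trade-offs within a subject beyond the error
  increment.
* Hierarchical (group-level) estimation, Bayesian arbitration variants
  of the WM/RL mixture, and negative-feedback-specific learning rates
  are out of scope.
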