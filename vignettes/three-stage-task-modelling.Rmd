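---
title: "Modelling arbitration between model-based and model-free control in a three-stage Markov decision task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling arbitration between model-based and model-free control in a three-stage Markov decision task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task

`threestage` simulates and analyses a two-choice, three-stage Markov decision
task. On every trial the agent starts in a single first-stage state, presses
left or right, transitions probabilistically to one of four second-stage
states, chooses again, and lands on one of eight terminal states carrying a
coloured coin worth 0, 10, 20 or 40 points. Value-0 coins are always grey;
the three reward-bearing values each carry one fixed colour.

Trials are organised in blocks crossing two factors:

* **Goal condition.** In *specific* blocks a cued colour is the goal and only
  coins of that colour pay out; in *flexible* blocks every coloured coin
  pays its face value. Specific goals favour planning over an internal model
  of the transition structure; flexible goals can be served by cached
  stimulus–response values.
* **Transition uncertainty.** Each (state, action) pair has a designated
  likely successor reached with probability 0.9 in *low*-uncertainty blocks;
  in *high*-uncertainty blocks both successors are equiprobable. The
  designation is fixed at tree construction; only the probability changes
  between blocks.

A session holds 14 blocks of each of the four types in uniformly random
order. Low-uncertainty blocks run 3–5 trials and high-uncertainty blocks
5–7, so a session has 280 trials in expectation
(`expected_session_length()`). An optional training phase (80 flexible + 20
specific trials) can be generated with
`simulate_subject(include_training = TRUE)`; it is flagged in the output and
excluded from fitting and metrics by `main_trials()`.

The exact layout of the original decision tree (number of second-stage
states, placement of coin values) is not recoverable from the published
description, so `build_default_tree()` uses one start state, four
second-stage states and eight terminals, with the four coin values placed
behind each first-stage action (`40, 20, 10, 0` on one side and
`10, 0, 40, 20` on the other). This asymmetric placement makes the optimal
action sequence unique for every goal under low uncertainty, which keeps
`choice_optimality()` well defined there. The topology, values and
value-to-colour binding are configurable.

## The two learners

**Model-free (SARSA).** State–action values are updated from
reward-prediction errors,
\[
\delta = r(s') + \gamma\,Q_{MF}(s',a') - Q_{MF}(s,a), \qquad
Q_{MF}(s,a) \mathrel{+}= \alpha\,\delta,
\]
with the discount factor fixed at 1 and coins delivered only at terminal
states (intermediate reward 0). Within a trial the first-stage update
bootstraps from the *pre-update* value of the second-stage pair (standard
SARSA ordering). Values start at 0. The learner is goal-blind: it sees the
goal-gated reward actually received, never the raw coin value.

**Model-based (forward learning + backward planning).** The learner knows
the tree topology but estimates the transition probabilities. Each observed
transition produces a state-prediction error \(\delta = 1 - T(s,a,s')\)
(the leading 1 encodes a working assumption of deterministic transitions);
the observed successor gains \(\eta\,\delta\) and the other successor of the
pair is rescaled by \(1-\eta\), which preserves the row sum exactly — the
raw increment alone would break row-stochasticity, and multiplicative
rescaling is the convention of the framework this task descends from. Action
values are produced on demand by a backward sweep from the terminals: with a
goal-conditioned reward map \(r\) (cued colour's coins in specific blocks,
all coloured coins in flexible blocks),
\[
Q_{MB}(s,a) = \sum_{s'} T(s,a,s')\bigl[r(s') + \max_{a'} Q_{MB}(s',a')\bigr].
\]
Planning runs at every trial start. Whether to replan between the two
choices of a trial is a genuinely open implementation question, but on this
architecture it is moot: the stage-2 values depend only on the
stage-2-to-terminal transition block and the goal map, neither of which
changes after the first transition of a trial, so the trial-start plan and
a mid-trial replan back the second choice identically.

**Choice rule.** Both learners choose through a softmax,
\(P(a) \propto \exp(\tau Q(a))\), computed in the log domain with
max-subtraction. \(\tau\) operates on the raw coin scale (0–40).

## Fitting

`fit_model()` estimates (learning rate, \(\tau\)) per subject and model by
minimising the negative log-likelihood of both choices of every trial with
Nelder–Mead, run from 200 random restarts by default. The search is
unconstrained in a transformed space: learning rates through a logistic map
to (0, 1), \(\tau\) through an exponential map capped at 100. Restart
initialisations are uniform over rate in (0.01, 0.99) and \(\tau\) in
(0.1, 30), drawn so that the first *m* restarts of a larger run coincide
with an *m*-restart run at the same seed. Each restart runs at most 500
simplex iterations at a relative function tolerance of 1e-8. Choice
probabilities are floored at 1e-12 before the log so single near-impossible
choices cannot dominate. AIC (\(2k + 2\,\mathrm{NLL}\)) and BIC
(\(k\log n + 2\,\mathrm{NLL}\), \(k = 2\), \(n\) = number of choices) are
reported for model comparison.

The likelihood replay exists twice: a general, readable R implementation
(`learner_trace()` + `choice_loglik()`), and a compiled replay specialised
to two-element successor pairs that `fit_model()` calls. The test suite
asserts exact agreement between the two routes, and checks the planner
against a brute-force expectimax enumeration and the fitted optimum against
a grid scan.

**Identifiability.** On the coin scale, \(\tau \gtrsim 2\) makes behaviour
near-greedy: most choices are predicted at probability above 0.99, the
likelihood flattens in \(\tau\) above the generating value, and the fitted
\(\tau\) has an unbounded upper tail (the learning rate still identifies
well). Recovery is excellent for \(\tau \le 1.5\) — medians within a few
percent for both models at 280 trials. The parameter-recovery harness
therefore draws generating \(\tau \sim U(0.2, 1.5)\), the regime in which
simulated choice stochasticity resembles the intermediate preference and
optimality levels humans show on this task, rather than near-greedy play.

## Arbitration metrics

With both models fitted independently, every choice receives two
likelihoods. A choice is labelled MB-dominant when the MB model assigns the
chosen action a strictly higher likelihood than the MF model; exact ties
(measure-zero in practice, but counted and reported) go to MF. **System
preference** is the percentage of MB-dominant choices in a condition;
**system switching** is the percentage of adjacent choice pairs — formed
within a condition's choices in session order, crossing block boundaries of
the same condition but never pairing across conditions — whose dominant
system differs. Both choices of a trial enter the sequence. The
pairs-denominator reading of switching is implemented; a share-of-switch-
events denominator would only rescale all subjects jointly.

`choice_optimality()` counts a trial as optimal when both chosen actions
attain the maximal expected goal-contingent reward under the trial's true
transition probabilities. Ties count as optimal by default, which matters in
high-uncertainty blocks of the default tree, where both actions at every
second-stage state share a successor pair and are therefore exactly tied; a
strict mode matches the lexicographically tie-broken sequence instead.

## The synthetic cohort generator

Synthetic subjects blend the two systems before the softmax,
\(Q = w\,Q_{MB} + (1-w)\,Q_{MF}\), with the MB weight allowed to differ
between goal conditions. This fixed-weight mixture is deliberately *not* a
reliability-based arbitration controller; it exists so that preference and
switching are exercisable with known ground truth. Both learners update on
every trial exactly as the fitted models would, so a weight of 1 or 0
reproduces the corresponding pure model choice-for-choice at the same seed.
Agents and fits receive derived, recorded seeds, making every cohort
reproducible from one master seed.

What the generator emulates: block structure, goal gating, transition
uncertainty, and subjects whose reliance on planning varies by condition.
What it does not emulate: reaction times, attention lapses, choice
perseveration, the cost of deploying model-based computation, or any
arbitration dynamics — so passing direction checks on synthetic cohorts
shows the pipeline's statistical machinery works, not that real patients
behave like mixture agents.

## What the direction checks can and cannot show

A cohort with an "arbitration ability" trait — more MB weight in specific
blocks, less in flexible blocks, and higher choice precision as ability
rises — reproduces two of the three published cohort-level signs: MB
preference is higher under specific than flexible goals, and MB preference
correlates positively with earnings in specific blocks.

The third sign (a *negative* correlation between MB preference and earnings
in flexible blocks) is not reproducible in this generative world, and the
corresponding acceptance check fails by design rather than being weakened.
The reason is structural. On the default tree, flexible-block earnings are
nearly policy-independent: half of flexible trials sit in high-uncertainty
blocks where both actions at every second-stage state are exactly tied, and
random choice already earns about 20.7 coins/trial against roughly 22 for
strong play. The residual dependence mildly *favours* MB weight, because
backward planning with a correct goal map is never detrimental, whereas
heavy MF reliance carries a real cost — its cached values are polluted by
interleaved goal-gated specific blocks. A negative sign would need
model-based control to be genuinely costly in flexible blocks, a feature
(computational cost, attention) that a self-consistent mixture of the
task's own two learners does not possess.

## Group statistics

`compare_groups()` reproduces the published analysis layout: pooled-variance
two-sample t-tests per measure (the pooled form reproduces the published t
statistics for both equal and unequal group sizes; Welch is available),
Benjamini–Hochberg FDR over the family of four measures within one
patient–control pair, and Cohen's d with the pooled SD. `pooled_t()` and
`cohens_d()` accept printed summary statistics (n, mean, SD) directly, so
published tables can be re-derived without raw data. The sex-covariate
analysis is implemented as the equivalent linear model
(`measure ~ covariate + group`) with a partial F-test for the group term.

## Problem sizes and run times

The test suite fits with 10–20 restarts instead of the study default of 200
(the restart draws are nested, so results at higher counts can only
improve), uses 50 subjects for parameter recovery, 30 for the direction
checks, and 20 replicate pipelines of 10 + 10 subjects for the null
calibration; the full suite runs in about five minutes on one core. All of
these sizes are configuration arguments, not limits of the implementation.
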