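---
title: "Incremental development, belief updating, and the evolution of sensitive periods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental development, belief updating, and the evolution of sensitive periods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensdev)
```

## The model

`sensdev` asks when natural selection favours *sensitive periods* —
stretches of ontogeny in which experience shapes the phenotype more than at
other ages — for organisms that build their phenotypes incrementally in an
environment that keeps fluctuating while they develop.

The world is a patch that switches between two states, `E0` and `E1`, as a
two-state Markov chain with per-period transition probabilities
P(E0|E1) and P(E1|E0). Development (*ontogeny*) lasts `T_ont` discrete
periods (10 by default). In each period the organism samples one cost-free
binary cue whose reliability is P(C0|E0) = P(C1|E1), updates its belief
about the current state by Bayes' theorem, and then takes one of three
actions: add one irreversible increment towards the specialist phenotype
`P0`, one towards `P1`, or wait. Increments can never be removed, but the
organism may switch which target it builds towards at any age. After
ontogeny comes adulthood (`T_adult` periods): the phenotype is frozen, the
environment keeps fluctuating, and each adult period pays

> baseline + reward(# correct increments) − w · penalty(# incorrect increments),

where "correct" means matching that adult period's environmental state and
`w` is the penalty weight. Fitness is fertility only; there is no
mortality, no cue cost, and no discounting.

### Beliefs: the hidden-Markov forward recursion

During ontogeny the environmental state is hidden and only cues are
observed, so the belief after any cue history is computed by the forward
algorithm: the prior at birth is the chain's stationary distribution
π(E0) = P(E0|E1) / (P(E0|E1) + P(E1|E0)) — the "evolutionary prior" — and
each period applies one Markov prediction step followed by one Bayes
update. Two conventions matter and are fixed throughout:

* **Period 1 applies no transition before the first cue**: the period-1
  predictive belief is the stationary prior itself.
* **The first adult period uses the final posterior directly**; adult
  period *i* propagates it *i − 1* further steps, converging to the
  stationary distribution. (The alternative — one extra transition into
  adulthood — shifts every adult distribution by one step and changes
  values only slightly; the convention here keeps the end-of-ontogeny
  posterior meaningful as "the state distribution the adult starts in".)

Beliefs are carried per cue history, never merged by value: the lattice at
period *t* has exactly 2^t nodes. This avoids any merging tolerance and
makes every downstream quantity an exact enumeration.

### The policy: exact backward induction

A decision state is (period, cue history, phenotype), with the phenotype
the pair (y0, y1) of increments built so far. The terminal value of the
final action is the expected fitness summed across adulthood; earlier
action values weight successor values by the predictive probability of
each next cue given the current belief. Because the state space is small
(≤ 2^10 histories × 66 phenotypes × 10 periods), the recursion is solved
exactly, with no function approximation and no sampling.

Tie-breaking: when action values tie within a relative 1e−12, the chosen
action is specialization towards the state with the higher posterior, then
`spec_P0`, then `wait`. Ties are genuinely reached (e.g. uninformative
cues in a symmetric environment make the two specializations exactly
equivalent), so all tied states are recorded in the policy object rather
than silently resolved.

### Measuring plasticity: the simulated adoption paradigm

Plasticity at age *t* is measured the way adoption/twin studies measure
it. For every possible cue sequence we create a pair of clones following
the same (optimal) policy. They share cues — and therefore decisions —
until period *t*; from *t* onward the copy develops in a mirror patch
receiving the reciprocal opposite cue in every period. Each pair is
weighted by the likelihood of the focal's cue sequence given the patch's
true starting state (the experimenter's frame; the organisms' beliefs
always start from the stationary prior). Plasticity at separation time *t*
is the weighted mean Euclidean distance between mature phenotype vectors
(y0, y1), divided by the maximal attainable distance √2 · (T_ont − t + 1),
so it lies in [0, 1].

"Separated at *t*" here means cues differ from period *t* onward
*inclusive*: separation at *t* = 1 yields fully divergent twins and
*t* = T_ont a single divergent cue. The alternative convention (shared
through *t*) would shift every curve by one period; ours keeps the final
separation time informative, which matters because a central result is
that plasticity never drops to zero there.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p_to_e0`, `p_to_e1` | — | per-period switch probabilities P(E0\|E1), P(E1\|E0); the study regime keeps both in (0, 0.5) (positive autocorrelation; values outside warn) |
| autocorrelation | 0.2 / 0.5 / 0.8 | 1 − P(E0\|E1) − P(E1\|E0); high = rare switches |
| asymmetry | 0 or 0.1 | P(E0\|E1) − P(E1\|E0); positive values make `E0` the majority state |
| reliability | 0.55 / 0.75 / 0.95 | P(correct cue \| state); 0.5 = uninformative, 1 = perfect |
| `T_ont` | 10 | ontogeny length (periods) |
| `T_adult` | 1 / 5 / 20 | adult lifespan; long adulthoods let the prior dominate |
| shapes, `penalty_weight` | linear/linear, 1 | reward/penalty curvature and mismatch weight |
| `baseline` | 0 | per-period fitness of a lifelong waiter |

The cumulative mapping family is f(y) = T_ont · (y/T_ont)^k with k = 1
(linear), 2 (increasing) and 0.5 (diminishing): all shapes are zero at
zero increments, reach T_ont at full specialization, and differ only in
curvature. This family reproduces the model's worked example exactly: with
linear shapes and weight 1, a balanced specialist (5, 5) and a lifelong
waiter (0, 0) both earn zero in every adult period, while weight 2 or a
diminishing penalty pushes the balanced specialist strictly below the
waiter. Baseline fitness is an additive constant that cannot change any
argmax, so it defaults to 0 and stays configurable.

## A worked run

```{r solve}
cfg <- run_config(autocorrelation = 0.8, reliability = 0.75,
                  T_ont = 10, T_adult = 5)
res <- run_solve(cfg)
res$root_value                 # expected terminal fitness at birth
head(res$table[, c("period", "belief", "reach", "y0", "y1", "action")])
```

With symmetric transitions, linear shapes and weight 1, the policy never
waits and always specializes towards the state with the higher posterior —
waiting buys information value that never exceeds the marginal reward of a
specialization that can still be redirected later.

```{r twin}
twin <- run_twin(cfg)
subset(twin$curves, start_env == "E0")$distance
```

The curve stays positive at every separation time — a *sensitive* period
(a maximum somewhere in ontogeny) without a *critical* period (plasticity
never collapses to zero before maturity). Zero plasticity does evolve, but
only when one state is more common and cues are poor or adulthood is long:

```{r nonplastic}
run_twin(run_config(autocorrelation = 0.5, asymmetry = 0.1,
                    reliability = 0.55, T_adult = 20))$nonplastic
```

```{r compare}
run_compare(run_config(autocorrelation = 0.5, asymmetry = 0.1,
                       reliability = 0.55, T_adult = 20))
```

In that regime the optimal policy coincides with the non-plastic
majority-state specialist, exactly as the comparison table shows.

## What the enumeration does and does not emulate

Everything shipped is an exact, deterministic computation: cue-sequence
enumeration with forward-algorithm weights replaces population sampling,
so "simulating 2^10 pairs of clones" is a weighted sum, free of
Monte-Carlo error, and identical runs are bit-identical. Monte-Carlo
counterparts (`sample_trajectory()`, `sample_trajectories()`) exist to
cross-check the closed forms and to handle ontogenies longer than the
enumeration limit (`T_ont` ≤ 14).

The model idealizes real development in ways that bound what passing
tests can show: two environmental states, one binary cue per period with
age-constant reliability, no cue costs, no mortality during ontogeny, no
learning of the environmental parameters themselves (organisms are born
knowing the transition probabilities and reliability), and fitness
accruing only in adulthood. Results are statements about optimal policies
under these assumptions, not about any particular species' mechanism.

## Numerical choices

* Backward induction and the forward lattice are exact to double
  precision; likelihood normalization is asserted at 1e−12 in tests.
* Action ties: relative tolerance 1e−12, deterministic preference order
  (higher-posterior specialization, then `spec_P0`, then `wait`), all ties
  recorded.
* Normalized distances are clamped to [0, 1]: with every pair at the
  normalization bound the weighted sum can exceed 1 by ~1 ulp.
* Propagation uses the eigenvalue closed form π + (b − π)·λ^n with λ the
  lag-1 autocorrelation, avoiding repeated matrix powers.
* Degenerate chains (both switch probabilities zero) have no stationary
  prior and are rejected where the prior is needed.

Problem sizes used throughout the shipped analyses: `T_ont` = 10 (1,024
cue histories, ~66 phenotypes), grids of 27 configurations; a full grid
with plasticity curves for both start environments completes in seconds.
The brute-force verification oracles enumerate all deterministic
history-dependent policies up to `T_ont` = 2 (3^6 assignments) and switch
to an independent depth-first tree search (beliefs recomputed from
scratch per path) for `T_ont` 3–4, where full policy enumeration is
combinatorially out of reach.

## Known limitations

* Exact enumeration scales as 2^T_ont; longer ontogenies need the sampling
  path and lose exactness.
* Only the reciprocal-opposite-cues, permanent-separation manipulation of
  the adoption paradigm is implemented.
* The reward/penalty family is one concrete instantiation of
  linear/increasing/diminishing curvature; alternative constants can be
  explored by supplying a different `fitness_mapping()`, but the shapes
  are fixed to power functions.
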