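---
title: "Dual-system arbitration: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-system arbitration: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

habitree simulates the competition between two reinforcement-learning
controllers over the same tabular task: a cheap, slowly adapting **habitual
cache** and an expensive, flexible **goal-directed tree**. This vignette
documents the model as implemented, the parameters that matter, the design
choices made where the design was genuinely open, and what the built-in
tasks do and do not establish.

## The two controllers

**Habitual cache.** One Beta posterior per (observed state, action),
initialised to the uninformative Beta(1, 1). On a non-terminal transition the
entry is updated toward the bootstrapped, cost-adjusted target mean
`μ̂ = γ·μ_{s',a*} + r_a` (the successor's greedy-action mean, discounted,
plus the executed action's reward), clamped to [0.001, 0.999]. The target is
expressed as a full distribution by holding one shape parameter of the
successor posterior fixed and solving `α̂/μ̂ = β̂/(1−μ̂)` for the other;
of the two candidates the **larger-variance** one is kept, on the view that
every bootstrap step adds uncertainty. The entry is then moment-matched to
the mixture `∫ Beta(α+x, β+(1−x)) Q̂(x) dx`. Terminal transitions use a
fractional Bernoulli update: `α += c`, `β += 1−c` with
`c = clamp(r_obs + r_a, 0, 1)`. The terminal rule is a design choice — the
cache cannot consult the reward model, and the fractional update is the
natural Beta-Bernoulli analogue for rewards in [0, 1].

**Goal-directed tree.** A Dirichlet row per (state, action) with symmetric
concentration `α_i` (default 0.1) and a Beta reward model per state. Planning
is value iteration on the row means,
`Q(s,a) ← r_a + γ·Σ_{s'} P̄(s'|s,a)·V(s')`, with `V` equal to the
reward-model mean at terminal states and `max_a Q` elsewhere, run to a
max-norm tolerance of 1e-4 (sweep cap 1000) at every consulted decision.

**Learned terminality.** The planner treats a state as terminal only after an
episode has actually ended there. Until then it is an ordinary state whose
value comes from its (mostly prior) transition row. This is deliberate:
goals the agent has never experienced must not act as planning targets.
Without it, an uninformative reward prior (mean 0.5) makes every unvisited
goal more attractive than a devalued one, and the devaluation experiments
lose their meaning — the agent "switches" to goals it has never seen. The
flip side is that first discovery of a goal is driven entirely by intrinsic
motivation and ε-exploration, which is the intended dynamic.

## Arbitration

For each action the value of perfect information is computed from the cache
posterior alone: `VPI(s,a) = ∫ G_{s,a}(x) p(Q^cache_{s,a} = x) dx` with the
usual two-branch gain against the best/second-best cache means (ties broken
by the fixed action order). The tree is consulted for an action iff
`VPI > R̄·τ`; equality resolves to the cache, the cheaper system. One value
iteration per decision serves all tree-selected actions. The average reward
is tracked per step as `R̄ ← (1−η)·R̄ + η·r_t` with `r_t` the extrinsic plus
action reward of the executed step; intrinsic rewards do **not** feed `R̄`
(it models tonic expectation of *environmental* income), and `R̄` starts at
0 — no expectation before experience. In *fixed* mode (`reward_mode =
"fixed"`) `R̄` reads as a constant (default 1), modelling a promised reward.

## Intrinsic motivation

Learning progress is the summed absolute shift of a transition row's mean
vector caused by its most recent observation, scaled by ι:
`I(s,a) = ι·Σ_{s'} |Δμ^trans|`. Under **local** scope the bonus is added to
the root tree values after the search; under **global** scope it is added to
every backup target (discounted along with the rest of the backup — the
undiscounted variant would make bonuses grow without bound along long
horizons, so the implementation keeps γ inside the global backup). Shifts
caused by forgetting decay are not counted: decay is homogeneous across the
table and would manufacture uniform spurious "progress". Because the stored
shift is a standing quantity until the pair is observed again, a long-unused
action whose row has decayed back toward its prior yields a large bonus when
finally re-executed; with strong forgetting (the feeder's θ = 0.98) this
produces a slow re-exploration cycle over neglected actions, visible as
occasional non-greedy-looking choices in otherwise settled runs.

## Forgetting

Every pseudo-count in both controllers decays once per environment step:
`p ← θ·p + (1−θ)·p_prior`. Devaluation replaces a goal's reward entry *and
its prior*, so decay cannot restore the old value. The Playroom θ = 0.9999
effectively disables decay (long episodes, large model); the feeder keeps
the inherited θ = 0.98.

## Default parameters

| Parameter | Symbol | Playroom | Feeder | Notes |
|---|---|---|---|---|
| Exploration | ε | 0.2 | 0.2 | ε-greedy over mixed Q-values |
| Search cost | τ | 0.1 | 0.1 | price per deliberation step |
| Intrinsic scale | ι | 2.0 | 2.0 | brings bonuses to reward scale |
| Discount | γ | 0.95 | 0.95 | see feeder notes below |
| Forgetting | θ | 0.9999 | 0.98 | per step |
| Avg-reward rate | η | 0.001 | 1e-4 | see feeder notes below |
| Transition prior | α_i | 0.1 | 0.1 | symmetric Dirichlet |
| Cache prior | — | Beta(1,1) | Beta(1,1) | uninformative |
| Reward-model prior | — | Beta(1,1) | Beta(1,1) | with learned terminality |
| Step cap | — | 100 | 50 | episode truncation |

**Feeder notes.** The feeder publishes only τ, ε and ι; the remaining values
are inherited or derived. Two deserve explanation. *Restart semantics*: a
failed sequence returns the agent to the start state within the same trial
(episodes end only at the rewarded terminals). This matters: it makes the
second-best action's value `γ²·V(optimal)` — close to the best — so the two
posteriors overlap persistently and the ambiguity VPI stays near 1e-3. With
restart-as-terminal instead, the runner-up collapses to ~0.2, the pressed
arm separates by many σ within 20 episodes, its VPI vanishes, and no
parameter setting reproduces early devaluation sensitivity. *η = 1e-4*:
feeder trials are two steps, so per-step reward rate is roughly 25× the
Playroom's; with a faster η the opportunity cost `R̄τ` overtakes the
ambiguity VPI long before extensive training, collapsing the early/late
distinction. At 1e-4 the crossing happens around episode 150, after moderate
training (20 episodes) but before the extensive mark (200).

## Numerical choices

* **Quadrature.** All Beta integrals (VPI, mixture moments) use a fixed
  512-node tanh-sinh rule on (0, 1). Tanh-sinh rather than Gauss–Legendre
  because shape parameters are generally non-integer (moment matching,
  decay), giving algebraic endpoint singularities that defeat polynomial
  rules at the required 1e-6 accuracy; the double-exponential clustering
  also resolves near-point-mass targets such as Beta(1e6, 1). The VPI
  integrand has a kink at the decision threshold, so the nodes are mapped
  onto the sub-interval where the gain is nonzero. A seeded Monte-Carlo VPI
  backend (`vpi(..., method = "mc")`) is available for fidelity to the
  "integration by sampling" description; the deterministic rule is the
  default because it removes sampling noise from arbitration.
* **Moment matching.** Mixture moments convert back to Beta parameters via
  `ν = m(1−m)/v − 1`; if the mixture variance is too large for its mean the
  parameters are floored at 1e-3 to keep the distribution proper.
* **Value iteration.** Tolerance 1e-4 in max norm, cap 1000 sweeps. Inside
  the simulation engine the previous decision's converged Q warm-starts the
  next search when γ < 1 — the backup operator is a contraction, so the
  fixed point is unchanged and this is purely a speed optimisation;
  the exported `value_iteration()` defaults to the cold start.
* **Ties.** Best/second-best use the fixed action order; exact ties in the
  greedy argmax are resolved uniformly at random from the run's RNG stream.
* **Clamps.** Bootstrap target means are clamped to [0.001, 0.999] (costs
  and discounts can push raw targets outside the Beta support); terminal
  update fractions to [0, 1].
* **Reproducibility.** All randomness flows from R's RNG; `agent_config(seed =)`
  seeds a run, and two runs with equal seeds are bit-identical.

## What the built-in tasks emulate — and what a green test establishes

The feeder emulates instrumental conditioning with devaluation probes:
short action sequences, a single rewarded outcome, and a devaluation that
replaces the outcome's reward distribution (and the delivered payoff) with
Beta(1, 15), mass near zero. The Playroom emulates free operant "play":
cyclic trajectories, one stochastic action (`eye_to_random`), action costs
that favour doing nothing (+0.005 for `null`, −0.02 otherwise), and partial
observability — with the light off the two boxes are indistinguishable, and
the agent's entire learning state is indexed by observed states while the
dynamics run on true states.

These are stylised worlds. A green experiment test establishes that the
*mechanisms* interact as described — cache dominance causes devaluation
resistance, learning progress raises activity until the model stabilises,
promised reward suppresses deliberation — under paired seeds and sign tests.
It does not establish quantitative correspondence with animal or human data,
nor robustness across task geometries beyond the two shipped ones.

Two caveats from the experiments themselves. First, with the goal "music on,
light off, eye on the blue box", a three-step stochastic shortcut exists
from a lights-off start (`eye_to_random` lands on the true blue box with
probability 1/4, then `hand_to_eye`, `use`), so the habitual cache can learn
this "distal" task without ever planning; the promised-reward performance
deficit is therefore directional (fixed-R̄ reach ≈ 0.62 vs ≈ 0.72 observed)
rather than the complete failure the mechanism would produce in a task with
no model-free route. The search-count reduction (~14×) is robust in every
seed. Second, under local scope, intrinsic motivation is myopic — bonuses
attach to the current state's actions only — so deep, never-rewarded regions
are discovered rarely; the distal-goal acquisition advantage of intrinsic
motivation is carried by the minority of seeds in which discovery happens at
all (it essentially never happens without intrinsic rewards, which is the
point of the comparison).

## Known limitations

* Exact-inference tabular learning only; no function approximation, no
  eligibility traces, no prioritised sweeping.
* The per-action system choice is independent across actions; once part of a
  state's actions go habitual, tree knowledge for them is ignored even when
  a search ran for a sibling action.
* θ must be tuned to task scale (0.98 forgets faster than the Playroom can
  learn); no surprise-modulated forgetting is implemented.
* Deliberation time is modelled only through the search count; no wall-clock
  or reaction-time claims.
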