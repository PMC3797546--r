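# habitree

Dual-system reinforcement learning with Bayesian arbitration: a simulator for
the competition between a **habitual** (model-free) and a **goal-directed**
(model-based) controller, of the kind used to model the dorsolateral and
dorsomedial striatal learning systems, extended with learning-progress
intrinsic rewards and per-action transition costs.

## The model

Both controllers are Bayesian. The habitual *cache* keeps a Beta posterior
`Q^cache_{s,a} ~ Beta(α, β)` over every action value; the goal-directed *tree*
learns a Dirichlet transition model and a Beta reward model per state and
plans by value iteration to convergence at every consulted decision.

Arbitration is per action, by the **value of perfect information**: the gain
of learning that action *a* truly has value *x* is

    G_{s,a}(x) = Q2 − x   if a is the current best and x < Q2
               = x − Q1   if a is not the best and x > Q1
               = 0        otherwise

with `Q1`, `Q2` the best and second-best cache means, and
`VPI(s,a) = E[G_{s,a}(x)]` under the action's cache posterior (a fixed
512-node quadrature). The tree is consulted for an action only when its VPI
exceeds the opportunity cost `R̄·τ` of deliberating, where the average reward
`R̄` is tracked as `R̄ ← (1−η)·R̄ + η·r` (or pinned at 1 to model *promised*
rewards). Cache entries learn from cost-adjusted bootstrapped targets,

    μ̂_{s,a} = γ·μ_{s',a*} + r_a ,

reshaped onto a Beta with the variance-increasing branch of
`α̂/μ̂ = β̂/(1−μ̂)` and folded in by the Dearden-style mixture update
`∫ Beta(α+x, β+(1−x)) Q̂(x) dx` (moment-matched). The tree additionally earns
an intrinsic **learning-progress** reward
`I_{s,a} = ι·Σ_{s'} |Δμ^trans_{s,a,s'}|` for the most recent shift of its
transition model, added to the root tree values (local scope) or to every
backup target (global scope). All pseudo-counts decay toward their priors
with a per-step forgetting factor θ.

Two tabular tasks ship with the package: a two-step **feeder** (lever press /
magazine entry, with failed sequences restarting the trial) and a partially
observable **Playroom** (hand, eye, two boxes that start/stop music, a light
switch that makes the boxes indistinguishable when off, and a toy monkey).
Seeded experiment harnesses reproduce outcome-devaluation resistance,
activity with and without intrinsic rewards, post-extinction activity drops,
local-vs-global motivation scope, distal-goal acquisition, and the
promised-reward speed/performance trade-off.

## Worked example

Devaluation resistance after extensive training on the simple feeder task:
the rewarded terminal is devalued to Beta(1, 15) after 200 episodes, and
behaviour is compared over the 100 cycles before and after.

```r
library(habitree)

reshape_to_mean(beta_dist(4, 4), 0.75)
#> Beta(4, 1.333)  mean 0.75  var 0.02961

env <- make_feeder("simple")
cfg <- feeder_config(seed = 42)
sched <- list(devaluation_event(env, 200, states = "T+"))
trace <- run_episodes(env, cfg, 300, sched)

s0 <- trace$obs_state == 1
rows <- seq_len(nrow(trace))
sd <- max(which(trace$episode <= 200))
mean(trace$greedy_action[s0 & rows > sd - 100 & rows <= sd] == 1)   # pre
#> 0.94
mean(trace$greedy_action[s0 & rows > sd & rows <= sd + 100] == 1)   # post
#> 0.66
mean(!greedy_used_tree(trace)[s0 & trace$episode %in% 181:200])
#> 0.92
attr(trace, "final")$tree_searches
#> 1536
```

The agent presses on 94% of start-state visits before devaluation and still
on 66% afterwards — the devaluation-resistant habit — because by episode 200
the habitual cache answers for the greedy action 92% of the time and the
goal-directed system (which would immediately propagate the devalued reward)
is rarely consulted. Devaluing after only 20 episodes instead produces an
immediate collapse of pressing (see `feeder_devaluation()`).

The Playroom experiments are driven the same way, e.g.
`activity_experiments(runs = 20, seed = 1)` or from the command line via
`inst/scripts/run_experiment.R activity --runs 20 --seed 1 --out results/`.

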