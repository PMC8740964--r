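---
title: "Cognitive cascades: model, methods and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive cascades: model, methods and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogcascade)
```

## The public-opinion-diffusion model

The simulator couples three ingredients: a *belief space*, an
*institutional broadcaster*, and a *contagion rule* governing adoption.

**Belief space.** Beliefs live on a discrete scale `0..R-1`
(`belief_space()`, default `R = 7`). Agents hold exactly one level at a
time; a message encodes exactly one level. The scale is ordinal: the only
quantity the model ever consumes is the absolute level distance
`d = |b_u - b_m|`.

**Institution and message sets.** One institutional agent holds a
perceived belief (default: the top level) and broadcasts one message per
timestep according to a schedule (`schedule_single()`, `schedule_split()`,
`schedule_gradual()`, `schedule_custom()`). Its audience is fixed at wiring
time: every agent whose initial belief is within `epsilon` of the
institution's subscribes (`wire_subscribers()`; default `epsilon = 0`).
The gradual schedule moves one level toward its destination every
`interval` timesteps and holds the destination once reached; with the
defaults (7 levels, `interval = 10`, horizon 100) the final level is held
from timestep 61 onward.

**Within-timestep cascade.** A broadcast is delivered to all subscribers.
Each delivery triggers an adoption trial; adopters jump to the message's
level and share the message with every neighbor, and the cascade runs to
exhaustion before the clock advances. An agent *believes* a given message
at most once — adopting also marks the message as processed, so cycles
terminate.

## Contagion rules

`contagion_spec()` defines five variants; `contagion_preset()` names the
canonical parameterizations.

* `simple`: adopt with constant probability `p` (default 0.15).
* `proportional`: adopt iff the fraction of your graph neighbors already
  holding the message's level is at least `ratio_alpha` (default 0.35).
  This rule is deterministic given the neighborhood, and by default
  evaluates *current* beliefs mid-cascade (`proportional_frozen = TRUE`
  switches to the pre-injection snapshot).
* `linear`: `min(1, 1 / (gamma + alpha * d))`.
* `threshold`: `1` iff `d <= gamma`.
* `sigmoid`: `1 / (1 + exp(alpha * (d - gamma)))`.

The package's reference rule, *defensive cognitive contagion* (DCC), is
the sigmoid at `alpha = 4`, `gamma = 2`:

```{r}
round(dcc_probability_matrix(), 3)
```

Distance 0 gives 0.9997, distance 1 gives 0.982, distance 2 sits exactly
at the sigmoid's midpoint 0.5, distance 3 gives 0.018, and anything
farther is below 0.001. Agents defend their beliefs against distant
messages while remaining persuadable in small steps.

When a non-default belief resolution is used, distance-scaled parameters
are rescaled by `(R - 1) / 6` (`scale_spec_for_resolution()`), so "two
levels on a 7-point scale" means the same relative distance on a 64-point
scale.

## Graph ensembles

Four families (`graph_spec()`, `build_graph()`), all with beliefs drawn
uniformly at random per node:

* **ER** `sample_gnp` with `rho = 0.05` (mean degree ~25 at `N = 500`);
* **WS** small world, `k = 5`, rewiring `0.5`. A ring lattice cannot give
  each node an odd number of nearest neighbors, so we follow the
  k-nearest-neighbor convention: `floor(k / 2)` neighbors per side,
  degree 4. This is the convention used by standard library
  implementations that accept odd `k`;
* **BA** preferential attachment with `m = 3`;
* **MAG** multiplicative attribute graph over the single belief
  attribute: edge `(u, v)` appears independently with probability
  `affinity[b_u, b_v]`. The default kernel `1 / (6 + 50 * (b_u - b_v)^2)`
  gives 0.167 at distance 0 decaying to 0.0006 at distance 6, producing
  strong belief homophily.

Homophily is quantified as the mean belief distance across edges
(`homophily_score()`). For independent uniform beliefs on 7 levels the
expectation is `112/49 ~ 2.29` regardless of topology; the MAG kernel
pulls it down to ~0.29.

## Numerical and engine conventions

**Wave-synchronous trials.** The cascade engine processes deliveries in
breadth-first waves. All trials in a wave are evaluated against the
beliefs as they stood at the start of the wave, and adoptions are applied
between waves. Uniform random variates are consumed in delivery order
(senders ascending, neighbors in adjacency order), which makes every run
bit-reproducible from `config$seed` while remaining fully vectorized — a
500-agent, 100-step DCC run takes well under a second.

**Retry policy.** By default an agent gets *one* adoption trial per
message (`retry_policy = "once"`), not one per delivery. This matters:
under per-delivery retrials an agent with `k` believing neighbors is
re-tried up to `k` times per wave, which inflates the far tail of the
sigmoid (a distance-4 agent at `beta = 3e-4` sees its effective
per-timestep adoption probability multiplied several-fold) and audibly
erodes the defended levels over a 100-step run — contradicting the
defensive behavior the rule is designed to produce. The once-per-message
policy preserves it; `retry_policy = "per-delivery"` remains available.
Note that *each timestep's broadcast is a fresh message*, so a standing
population of believers re-exposes its neighbors once per timestep either
way; this slow repeated exposure is what moves midpoint agents (distance
3) over tens of timesteps, and at the probability tail it can move a few
distance-4 agents per run.

**Replicates.** `run_batch()` runs replicate `r` with seed
`config$seed + r`: adding replicates never perturbs earlier ones, and any
single replicate can be reproduced in isolation.

## Analysis apparatus

**Path probability.** A message survives a path of agents only if every
agent on it adopts; `path_probability()` multiplies the per-agent
single-exposure probabilities. Under DCC a single agent at distance 3
caps any path at 0.018.

**Believing neighbor sets.** `believing_neighbor_set()` finds, for each
neighbor `v` of a target, the maximum-probability institution-to-`v` path
(shortest-path search under `-log beta` arc weights, with the institution
added as an auxiliary vertex) and keeps neighbors above a credibility
floor `1 - delta`.

**Qualifying-path census.** `path_census()` asks a coarser question over
a graph ensemble: does *any* path run from the institution to a neighbor
of a randomly chosen target agent using only agents within belief
distance `tau` of the message (target excluded)? The default method
answers it exactly as reachability on the induced subgraph of qualifying
agents. `method = "dijkstra"` instead reproduces a min-sum shortest-path
heuristic (arc weight = belief distance of the entered agent) that checks
the bound only on the single returned path — it can miss qualifying paths
and therefore under-counts; it is retained for comparison with analyses
that used it.

**Timeseries comparison.** `avg_pearson()` correlates the per-level
fraction-believing series of two runs and averages across levels; levels
constant in either input are excluded (correlation is undefined there),
and the result is `NA` when no level moves — e.g. under the proportional
rule at the defaults, where no quorum is ever met. `chi2_timeseries()`
reports the fraction of timesteps at which a two-sample chi-squared test
fails to reject homogeneity of the two belief histograms: 1 means the
runs are statistically indistinguishable at every step. Because the test
is run per-timestep at a fixed significance level, values near 0.95
rather than 1.0 are expected even for identically distributed runs.

## Problem sizes and limitations

The canonical experiment (500 agents, 100 steps, 10 replicates) runs in a
few seconds; the full 36-cell grid in a few minutes; censuses cost one
graph build plus one components call per graph. The model deliberately
omits: agent-to-agent message *generation* (only institutions inject),
dynamic rewiring of the social graph, empirical network ingestion, and
optimization over message sequences. Within-timestep cascades assume
message propagation is fast relative to belief drift; the believe-once
rule assumes agents recognize messages they have already processed.
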