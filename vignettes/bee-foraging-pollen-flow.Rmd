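---
title: "Model and methods: reinforcement-learning bee foraging and pollen flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: reinforcement-learning bee foraging and pollen flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeflow)
```

## The question

Pollen moves between plants because pollinators move between plants, and
pollinators do not move at random: bees learn which flight vectors pay off
and develop repeatable multi-destination routes (traplines). `beeflow` is
an agent-based model that couples a reinforcement-learning movement model
of central-place foraging bees to a geometric pollen-carryover rule, so
that the consequences of pollinator cognition — spatial segregation under
competition, route fidelity, heterogeneous pollen flows — can be traced
all the way to plant mating patterns (mating distance, self-pollination,
mate diversity, pollen-network modularity).

## The world

Time advances in discrete 5-s steps. The arena is a square of side
`side_length` (default 1000 m) with continuous coordinates; the nest sits
at the origin and `n_plants` plants (default 20) are placed uniformly at
random. Because the arena size is fixed, raising the plant count raises
plant density. Each plant holds up to `n_max` µL of nectar and, whenever
below capacity, refills linearly so that a plant emptied at time $t$ is
full again at $t + \text{renewal\_duration}$. Renewal is continuous — a
partially depleted plant refills at the same per-second rate — which is
the simplest rule consistent with linear refill to capacity and avoids an
"armed only when emptied" special state.

## The bee

A bee knows all plant positions from the start; what it learns is the
*value* of transitions. For the ordered node pair $(A, B)$ (nest = node
0), a static discovery prior
$p_d(A,B) \propto 1/d(A,B)^2$, row-normalized to sum to 1, stands in for
the chance of finding $B$ from $A$ by random search. Expected transition
values start at

$$Q_0(A,B) = \tfrac{1}{2}\, n_{\max}\, p_d(A,B),$$

the value of a half-full plant discounted by its discoverability. On
realizing the transition $A \to B$ the bee perceives
$v = n_t(B)\, p_d(A,B)$ — nectar standing at arrival, before harvesting —
and updates

$$Q \leftarrow \alpha v + (1 - \alpha) Q,$$

with learning rate $\alpha \in [0,1]$; $\alpha = 0$ freezes the prior
exactly (a useful non-learning control: the final Q-table is
bit-identical to $Q_0$). Negative reinforcement is implicit: experiencing
$v < Q$ lowers $Q$ by the same rule.

Destinations are drawn by softmax,
$P(B) \propto \exp(\beta Q(A,B))$, over the plants not currently excluded
by a 60-s working memory (plants whose last visit completed less than
`wm_span` seconds ago) and excluding the plant the bee is standing on. We
use the max-subtraction form since $\beta Q$ can reach tens of units.
A bout ends — with a forced, rule-driven straight flight home that is not
a softmax decision and triggers no Q update — when the crop is full
(capacity 5 full plant loads) or when the chosen next leg would push the
distance flown this bout beyond `max_bout_distance`. At the nest the bee
unloads, grooms, waits `nest_wait` seconds, and departs again via a
softmax over the nest row of its Q-table (which is initialized and
learned exactly like plant rows; only the homing direction is
rule-driven). If every plant is in working memory at a decision point,
the bee returns to (or waits at) the nest — a fallback that only matters
in tiny arenas.

Bees due to act in the same timestep are processed in a freshly drawn
random order, so no bee has a systematic index advantage when two arrive
at the same plant. Travel takes $\lceil d / (5\,\text{s} \cdot
\text{speed}) \rceil$ timesteps; perception, learning, pollen exchange,
harvesting, and the next decision all occur within the arrival timestep.

## Pollen

Every plant visit, the bee first deposits a fraction $p$ of each carried
pollen lot onto the current plant, then picks up one fresh unit from it.
A lot picked up at plant $X$ therefore deposits $p$ on the next plant
visited, $p(1-p)$ on the one after, then $p(1-p)^2$, and so on — the
geometric carryover kernel. Deposits below 0.01 units are not recorded
(the lot still decays, and lots that can never again produce a
recordable deposit are pruned; a brute-force re-walk oracle in the test
suite confirms the recorded ledger is unchanged by pruning). Revisiting a
plant while still carrying its own pollen records a donor = recipient
event — this is precisely what the self-pollination rate measures. Pollen
is unlimited at the source and unbounded on the bee; grooming at every
nest return prevents any cross-bout carryover.

## Metrics

Foraging metrics are taken at the 29th bout (later bouts are not
completed in every run): visits per bout (revisits included), nectar
intake rate (µL collected / bout duration), and the similarity index
between bouts 28 and 29. The similarity index enumerates all windows of 3
consecutive plant visits (2 transitions); a transition is *shared* when
it lies inside a window occurring contiguously in both bouts, and

$$SI_{ab} = \frac{s_{ab}}{2\, l_{ab}},$$

with $s_{ab}$ the shared-transition count summed over both bouts and
$l_{ab}$ the transition count of the longer bout — so identical bouts
score exactly 1 and subsequence-disjoint bouts 0. The pairing
(28, 29) rather than (29, 30) is used because bout 30 is the one most
often missing.

Window metrics use the final 5000 s: the local intensity of competition
$I_{loc}[i] = N_v[k \neq i] / (N_v[i] \cdot N_i)$ (competitors' visits to
the focal bee's plant set, normalized by the bee's own visits and plant
count), per-plant visit/visitor counts, the pollen-weighted *lower*
median mating distance over donor–recipient pairs (self-transfers at
distance 0 are excluded — they are already captured by the
self-pollination rate; a flag restores them), the self-pollination rate
(own / total pollen received per plant), mate diversity (distinct
non-self donors per recipient, magnitude deliberately ignored), and the
modularity of the weighted donor × recipient pollen network.

Modularity is Barber's bipartite $Q$ maximized by label propagation with
whole-module merge moves and multiple restarts over a grid of initial
module counts (20 by default), then normalized by the $Q$ the same
partition attains on the idealized network with all between-module
weight removed, giving $Q_{norm} \in [0,1]$: 1 when every donor group
feeds an isolated recipient group, 0 for structureless networks (also the
convention when the idealized modularity degenerates to 0). Ties in
label propagation keep the current label, otherwise the smallest label
id, so a run is deterministic given the RNG state; on all matrices up to
4 × 4 the optimizer provably attains the exhaustive-search optimum (the
suite enumerates every set partition).

## Experiment design

The baseline crosses renewal duration {200, …, 1200 s} with
$\alpha \in \{0, 0.5\}$ for 2 bees on 20 plants; sensitivity axes cover
bee count, plant count (20 vs 40), $\beta$ (10 vs 20) and $p$ (0.25 vs
0.5). Each condition runs on 25 randomly generated environments
(seeds `master_seed + environment index`, shared across conditions) with
50 replicates each — 1250 simulations of 40,000 s per combination. Run
seeds derive from the master seed and the (combination, environment,
replicate) indices through a Lehmer-style hash modulo $2^{31}-1$, so
sweeps are reproducible and resumable; the bee-count grid defaults to
{1, 2, 4}.

## Parameter defaults and calibration

Several physiological constants are free parameters of the model; the
package fixes one documented default apiece and exposes all of them in
the configuration objects.

| parameter | default | rationale |
|---|---|---|
| `side_length` | 1000 m | bumblebee-scale foraging range |
| `n_plants` | 20 | baseline scenario |
| `n_max` | 8 µL | see calibration note below |
| `crop_capacity` | 5 · n_max = 40 µL | five full plant loads |
| `speed` | 3 m/s | typical loaded bumblebee flight speed |
| `max_bout_distance` | 3000 m | ~2–3 typical 5-visit bouts of slack |
| `nest_wait` | 300 s | unloading plus rest between bouts |
| `beta` | 10 µL⁻¹ | baseline exploration–exploitation |
| `p` | 0.5 | baseline deposition rate |
| `wm_span` | 60 s | working-memory span |

Two calibration points deserve emphasis because they are *structural*,
not cosmetic. First, $\beta$ carries units of 1/µL, so the dimensionless
product $\beta \, n_{\max}$ — not either number alone — sets how
deterministic choices are: learned preferences scale as
$e^{\beta n_{\max} p_d}$ and the initial prior spread as half that
exponent. With `n_max` of order 10 µL or more at $\beta = 10$, even the
prior is effectively an argmax and learning cannot change behaviour;
with `n_max` near 1 µL, learned and unlearned bees are equally random.
The default `n_max = 8` µL places the model in the regime where the
sensitivity contrast $\beta = 10$ vs 20 is meaningful: priors are
exploratory ($\beta Q_0$ spreads of a few units) while a learned, full,
nearby plant is strongly preferred ($\beta Q \approx 20$–30). Second,
the renewal sweep 200–1200 s is meant to bracket the bout cycle, and the
29th-bout convention implies roughly 30–45 bouts per 40,000 s, i.e. a
cycle of ~900–1300 s; `speed = 3` m/s and `nest_wait = 300` s produce
exactly that range (the distance cap bounds a bout's flight below
(3000 m + one homing leg)/3 m s⁻¹ ≈ 1470 s, so bout 29 is reached in
every run). All of these are configuration values, so any other regime
is one argument away.

## What the synthetic environments do and do not emulate

Generated environments capture plant geometry, density, and nectar
renewal — the features the model's mechanisms act on. They do not
represent landmarks, wind, flower-level structure within plants, nectar
quality variation, pollen depletion or pollinator pollen-carrying
limits, navigation error, or communication between foragers; the
geometric carryover kernel is also known to underestimate long-tail
pollen deposition. Results on these environments therefore demonstrate
the *mechanistic* consequences of learning under competition, not
field-calibrated predictions: passing tests show the implementation
realizes the stated model, and that the qualitative orderings (learning
raises intake rate and route similarity, lowers local competition,
lengthens mating distance, lowers self-pollination at slow renewal) are
robust at the default calibration — not that real meadows behave
quantitatively like the defaults.

## Numerical conventions

Times are internally integer timesteps; logged times are seconds
(multiples of 5). Travel time rounds up, never down, so a leg always
takes at least one step. The working-memory test is strict
(`now − t < span` excludes), so a plant becomes available exactly at the
span boundary; since the return leg itself takes ≥ 1 step, observed
same-plant revisit gaps always exceed the span. The Q update with
$\alpha = 0$ is exact in floating point ($0 \cdot v + 1 \cdot Q$), which
is why the non-learning control can be asserted bit-identical. The lower
weighted median is used for mating distance (deterministic under ties).
Degenerate cases reported as missing rather than fabricated: zero-length
bouts (intake rate), bees absent from the analysis window ($I_{loc}$),
plants that received no pollen (self-pollination, set against a defined
0 for "received but no self pollen"), empty transfer windows (all
pollination metrics).

## A worked run

```{r example, eval = FALSE}
env <- generate_environment(n_plants = 20, seed = 1)
sim <- run_simulation(env, bee_sim_config(alpha = 0.5), seed = 42)
metrics <- compute_all_metrics(sim)
metrics$summary
```

The scaled-down experiment used by the package's own validation (and by
`scripts/acceptance.R`) runs 25 environments × 5 replicates for
$\alpha \in \{0, 0.5\}$ × renewal $\in$ {200, 600, 1200} s — 750
simulations — and checks the qualitative orderings above; the full
25 × 50 design is one `bee_sweep_config()` call with the default
replicate count.

## Known limitations

Single-season, single-generation pollen flows only; no seed/fruit set
model; plant "individuals" are points without floral architecture; the
modularity optimizer is a stochastic local search (guaranteed optimal
only at the small sizes where it is cross-checked exhaustively, hence
the multi-restart default); and all defaults for unpublished
physiological constants are package choices, documented above, not
field measurements.
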