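---
title: "Boolean network dynamics and in-silico cell-fate reprogramming with refate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean network dynamics and in-silico cell-fate reprogramming with refate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refate)
```

## The model

`refate` simulates signed Boolean regulatory networks under a synchronous
update scheme. A network state is the binary vector of all node activities.
For an ordinary node $i$ with signed inputs $a_{ij} \in \{+1, -1\}$, the input
sum at time $t$ is

$$F_i = \sum_j a_{ij}\, S_j(t),$$

and the next state is 1 if $F_i > 0$, 0 if $F_i < 0$. When activation and
repression balance exactly ($F_i = 0$) the node's *self-mode* decides:
*self-degradation* turns the node off (a proxy for active protein turnover),
*self-sustaining* keeps the current state (constitutive expression), and
*self-activation* turns the node on (unmodelled activating input). Nodes of
kind `logic_and` and `phenotype` are conjunctions: they switch on only when
every parent was on at the previous step. This is deliberately outside the
weighted-sum rule — a conjunction over arbitrary fan-in cannot be expressed
as a threshold over $\pm 1$ weights with the zero-tie conventions above.

Two clamp mechanisms are distinct by design. A **clamp** fixes a node at
every step and models deletion (`0`) or constitutive overexpression (`1`)
mutants, as well as the environment signals set by a `condition()`. A
**transient override** sets a node only in the initial state and models the
transient perturbations used to reprogram cells; the network is free to
overwrite it from the first update on.

Synchronous dynamics on a finite state space always ends in a fixed point or
a limit cycle. The engine detects cycles of any period; because the
biological discussion is phrased in terms of fixed points, attractor
classification treats a cycle as *sporulation* only if the phenotype node is
on in every cycle state and as *cell cycle* only if all markers match in
every cycle state.

## Attractors, basins, and classification

`sample_attractors()` draws uniform random initial states over the free
(non-signal) nodes, evolves each to its attractor, and grows the sample in
batches (default 5000) until no class fraction changes by more than `tol`
(default 1%) between consecutive cumulative tallies — the convergence rule is
part of the method, not an implementation convenience. `enumerate_attractors()`
computes exact basins for networks with up to 22 free nodes and serves as the
oracle for the sampler in the test suite.

Attractor classes are defined by markers. Under the growth condition the
largest-basin attractor is the stationary G1 state; the protein nodes that
change at least once along the excited trajectory launched from it (cell-size
signal pulsed at $t = 0$) are the cyclic markers. An attractor is
*sporulation* when the SPOR phenotype node is on, *cell cycle* when every
marker equals its stationary-G1 value (all other nodes free), and *other*
otherwise. We read "cyclic change" as change along the excited trajectory
rather than across whole-basin trajectories; the alternative reading would
make the marker set depend on sampling depth.

## Phase assignment and viability

Each marker node $i$ carries a weight $w_{ij} \in [0, 1]$ for every
cell-cycle phase $j$ (START, G1, S, G2, M, stationary G1). A state $s$ scores

$$g(j) = \prod_i \big(s_i w_{ij} + (1 - s_i)(1 - w_{ij})\big),$$

normalized to sum to one across phases; the state is assigned to the argmax
phase (ties resolve to the earliest phase in canonical order and are
flagged). `derive_phase_weights()` initializes the weights from the network's
own labeled excited trajectory (phase-mean activity mapped onto
$[0.1, 0.9]$) and then applies a small deterministic calibration — the
programmatic counterpart of adjusting individual weights from 1 to 0.8 or
from 0 to 0.1 by hand — until every trajectory state is assigned its own
label. The calibration converges on both packaged fixtures.

A mutant is called **viable** when, launched from the START state with its
clamps applied, (i) the trajectory converges to a cell-cycle attractor and
(ii) the collapsed phase sequence is exactly
START–G1–S–G2–M–(G1)–stationary G1, the post-mitotic G1 being optional.
Runs of equal phases are collapsed because phase duration need not equal the
number of synchronous steps. The launch state itself (size signal on, marker
values still at rest) is dropped before assignment since markers cannot
distinguish it from stationary G1.

## Reprogramming

A recipe is a set of 1–4 perturbable proteins, each overexpressed (`OE`,
initialized to 1) or knocked down (`KD`, initialized to 0), applied
transiently. For 42 perturbable proteins there are
$\sum_{k=1}^{4} \binom{42}{k} 2^k = 1{,}886{,}248$ recipes;
`enumerate_recipes()` yields them deterministically and in chunks so screens
can be sharded. **Potency** is the fraction of random initial states a recipe
drives into the target class under a condition; *reprogramming achieved*
means the target-class fraction strictly exceeds the opposite class's
fraction (our reading of "reverses the percentages").

**Commitment** is measured by harvesting the initial and on-path states of
trajectories that converge to sporulation attractors under the sporulation
condition, recording each state's evolving distance $d$ to its attractor,
then re-evolving every harvested state under growth. States with $d \le 4$
that the bare condition switch fails to reprogram form the committed set;
**efficiency** is the fraction of committed states a recipe converts to
cell-cycle attractors. The **heterogeneity profile** is the distribution of
reprogrammed cells over the wild type's cell-cycle attractors, and the
**heterogeneity deviation** is the total-variation distance between
renormalized profiles, $\tfrac12 \sum_i |w_i - x_i|$ — chosen because it is a
true metric on distributions, bounded in $[0, 1]$, and zero exactly at full
restoration; the implementation isolates it so a Euclidean variant can be
swapped in. `pareto_front()` extracts recipes non-dominated in (efficiency,
deviation).

## Landscape and flux

`build_state_graph()` collects the states on evolving paths from seed states
(plus random padding up to a target size, default 10,000), and
`transition_matrix()` makes the dynamics noisy: node $i$ takes its
deterministic next value with probability
$(1 - c)\,\sigma(\mu |F_i|) + c/2$ for $F_i \ne 0$ (logistic $\sigma$,
sharpness $\mu = 5$, noise floor $c = 0.001$ by default) and
$(1 - c) + c/2$ toward the mode-resolved value on ties; clamped nodes are
noiseless. The probability of a joint transition is the product over nodes,
evaluated for in-graph states within Hamming radius 2 of the deterministic
successor (configurable); all remaining mass flows to a single pseudo-state
that represents every out-of-graph state and returns uniformly to the graph.
This closure keeps every row stochastic. As $\mu \to \infty$, $c \to 0$ the
matrix recovers the deterministic successor map — a limit the tests pin.

Steady-state probabilities come from power iteration of $p \leftarrow pT$
with an L1 stopping rule (default $10^{-12}$; deliberately conservative since
the per-iteration change understates the error when the spectral gap is
small). The potential of a state is $U = -\ln \bar p$, with $\bar p$ the mean
steady-state probability across the growth, sporulation and no-signal runs;
states absent under a condition contribute zero.

`reprogramming_graph()` evolves random initial states under a recipe and a
target condition, counting for each state how many *reprogramming paths* —
trajectories that end in the target class — pass through it; the normalized
flux divides by the number of states in the graph. Transition states are
accepted when their cumulative path count across the recipe ensemble and
their ensemble-mean normalized flux clear the thresholds (defaults 9,000
paths and 0.05). We read the path threshold as cumulative across the
ensemble: per-graph, 9,000 of 10,000 paths would be unreachable for any
state shared across heterogeneous recipes. A `per_graph` flag exposes the
alternative.

## Null models

`randomize_network()` performs sign-stratified double-edge swaps: two edges
of the same sign exchange targets unless that creates a self-loop or
duplicate pair. This preserves every node's in-degree, out-degree, incoming
activator count and incoming repressor count, and never touches edges into
conjunction nodes, whose wiring is part of the model semantics.
`null_distribution()` evaluates an arbitrary network metric over a
counter-seeded ensemble (draw $i$ uses seed $\mathit{seed} + i$, so draws do
not depend on ensemble size) and reports parametric and add-one-smoothed
empirical p-values; both are given because an ensemble of $10^4$ draws cannot
certify tail probabilities far below $10^{-4}$ empirically.

## The packaged networks

`yeast_cc11()` is the classic 11-protein budding-yeast cell-cycle Boolean
model plus a cell-size launch signal. Under this package's update rule it
reproduces the published basin structure exactly — seven fixed points with
basins 1764/151/109/9/7/7/1 of the 2048 states — which doubles as an
independent validation of the engine.

`yeast56()` is a **synthetic reconstruction** of a 56-node network coupling
that cell-cycle engine to the sporulation program (44 proteins/complexes,
5 AND nodes, the EMG/MMG gene groups, the cAMP/PKA pathway node, the SPOR
phenotype and 3 signals; 42 proteins are perturbable). Its edge list was
assembled from published interaction descriptions, not transcribed from any
single supplementary table; every edge carries a `provenance` tag (`core`
for the cell-cycle engine, `main_text` for interactions named in the primary
description of the coupled system, `synthetic` for the reconstruction's own
connecting choices). Design choices that shape its dynamics:

* the early-meiotic gene group EMG, together with the Ndt80/Ime2 positive
  feedback, forms a latch that survives a switch back to growth once
  engaged — this produces commitment: harvested sporulation-basin states
  within 4 evolving steps of their attractor are essentially never
  reprogrammed by a condition switch alone;
* the input-free repressors/activators Tup1, Gcn5 and Sum1 are
  self-sustaining, so a transient override of them persists — the discrete
  analog of an epigenetic flip, and the reason knockdown-containing recipes
  are potent;
* glucose repression runs through both the Mig1:Tup1 complex and a direct
  Mig1 route to Rpd3, so growth medium resists sporulation even when Tup1
  happens to be off.

At fixture scale the reconstruction yields: growth-condition basins of
roughly 48% cell cycle, 36% sporulation, 16% other over 10 cell-cycle
attractors; a sporulation-condition sporulation basin near 78%; 16 cyclic
markers; a viable wild type with the canonical phase sequence; and named
recipes with potencies near 100% (mixed OE+KD), 96% (knockdown-only) and 45%
(overexpression-only) — the mixed > KD-only > OE-only ordering that motivates
searching combined recipes. Published figures for the original curated
network (70%/16%/14% basins, 27 markers, 12 attractors, potencies
97%/85%/48.7%) are close in structure but not matched exactly; the
reconstruction's marker set is smaller because its sporulation side does not
cycle, and its growth-condition sporulation basin is larger. Tests that
depend on those exact published values document the discrepancy rather than
asserting around it.

## What the synthetic generator does and does not emulate

`generate_synthetic_network()` draws simple signed digraphs with chosen
density, activator fraction and self-mode mix. It emulates the combinatorial
structure the algorithms must cope with — multiple attractors, limit cycles,
heterogeneous tie-breaks — and is the workhorse of the oracle-equivalence
tests (200 random networks of 6–11 nodes are checked against exhaustive
enumeration). It does not emulate the modular, signal-gated architecture of
real regulatory networks, so passing those tests validates the *engines*,
not any biological claim; biological structure enters only through the
packaged fixtures.

## Numerical and scale choices

Sampling defaults follow the method's published settings (batches of 5,000
with a 1% convergence rule; 10,000 states for potency and efficiency
estimates). The test suite and the acceptance script run the same procedures
at 400–10,000 samples per call so the whole suite completes in minutes on a
single core; the vignette quotes the fixture-scale numbers those runs
produce. Exhaustive enumeration is capped at 22 free nodes; the full
1.9M-recipe screen is exposed as a chunked iterator rather than run wholesale.

## Worked example

```{r example, eval = FALSE}
net    <- yeast56()
scheme <- derive_scheme(net, n_init = 10000, seed = 1)
grow   <- condition(net, "growth")

# basin structure under growth
sample_attractors(net, grow, seed = 1, batch = 10000, cap = 10000,
                  tol = 1, scheme = scheme)$fractions

# the headline mixed recipe, applied transiently
potency(net, recipe("GCN5:OE+RPD3:KD+SUM1:KD+TUP1:KD"), grow,
        "sporulation", scheme, n = 10000, seed = 1)$potency

# commitment and an iPS-style reversal
cs <- commitment_analysis(net, scheme, n_init = 3000, seed = 1)
efficiency(net, recipe("IME2:KD+MIG1:OE+RPD3:OE+TUP1:OE"), cs, scheme,
           n = 10000, seed = 1)
```

## Known limitations

Only synchronous updating is implemented; asynchronous schemes can change
basin structure. The noisy transition model's exact per-node form and the
pseudo-state closure are this package's documented constructions (the
published description delegates to external material); they are pinned by
the zero-noise limit and row-stochasticity contracts rather than by an
external reference implementation. The packaged 56-node network is a
reconstruction: quantities tied to the original curated edge list should be
treated as qualitative.
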