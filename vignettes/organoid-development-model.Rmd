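---
title: "Modeling layered neural tissue development with organoidsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling layered neural tissue development with organoidsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidsim)
```

## The modeling approach

`organoidsim` treats tissue development as a discrete event system on a
finite 3D integer lattice. Nothing happens between events: every cell
action — secreting a factor, moving, dividing, differentiating, dying,
extending an axon — is an owner-bound event drained from a queue at its
due tick. Space uses the Chebyshev metric, so a "step" reaches any of the
26 surrounding coordinates, and a coordinate holds at most one cell body;
axon segments and sizeless spatial marks share coordinates freely and
never block movement.

Cell behavior is attached exclusively through *signaling pathways*: a
fixed built-in mechanism plus parameters, a trigger (cyclic with a
period, or conditional), a guard predicate, and an optional stochastic
gate. Guards are AND/OR trees whose leaves compare a factor concentration
(at the cell's own coordinate, or summed over a Chebyshev ball of radius
`r`) against thresholds; lower bounds use `>=` and upper bounds `<=`, so
a concentration exactly at threshold satisfies the condition. This
predicate-configured design means a new experiment is a new configuration
document, never new code.

### Determinism

All stochastic choices (daughter placement, target selection among
intersecting differentiation intervals, gradient-candidate choice,
stochastic gates) draw from R's RNG in a canonical order: events within a
tick execute in (priority, insertion) order, with lower priority values
first so destructive mechanisms (death, division) resolve before
constructive ones (growth, secretion). Independent events commute, so
this single deterministic order also serves as the conflict-resolution
rule for interdependent events — two movers claiming one coordinate
resolve in favor of the earlier-ordered event, and the loser re-evaluates
next tick. We deliberately break equal-priority ties by insertion order
rather than an extra RNG draw: it preserves replay determinism with one
stream and makes logs easier to diff. A fixed (configuration, seed) pair
therefore replays to a byte-identical event log, which the test suite
asserts.

One semantic worth knowing: after a division completes, both daughters
*relaunch their initial pathways* (the parent's frozen events are
discarded). A relaunched cyclic pathway first fires one `start_delay`
after completion (default 1 tick), so the effective division cadence is
governed by the division `duration` parameter plus that delay; the cyclic
`period` paces the initial firing and guard retries.

## Factor fields

Each factor has an emission radius (truncation support), a per-secretion
`signal_power`, a `propagation_rate` (the per-step variance of the 3×3×3
discrete-Gaussian diffusion kernel) and a `degradation_rate`
(multiplicative decay per tick). Numerical choices:

* **Reflecting walls.** The convolution conserves mass at lattice walls
  and leaves constant fields exactly invariant; the dense-convolution
  oracle in the tests agrees to 1e-9 over repeated steps.
* **Truncated support.** Concentration is clipped to the union of
  emission-radius balls around past sources after every step — signals
  simply do not exist beyond their significant action radius, which keeps
  fields sparse and guard evaluation local.
* **Pruning floor** of 1e-12 concentration units prevents unbounded
  accumulation of numerically negligible entries.
* Diffusion and degradation are applied once per tick per active field by
  the engine itself (equivalent to a cyclic field event with period 1);
  fields with zero mass are skipped.

Gradient following keeps every vacant neighbor whose concentration
satisfies the rule's bounds, prefers strict improvement along the chosen
direction, falls back to equal-concentration neighbors on plateaus, and
picks uniformly among what remains — so a flat field yields an unbiased
random walk and a strict gradient is always climbed.

## The organoid configuration

`make_organoid_config()` builds a complete experiment that grows a
layered structure from one neural stem cell (NSC). All of its numbers are
the package's own parameterization, chosen to produce the qualitative
architecture (bounded size, sequential outer-to-inner layer
differentiation, ordered radial layers, glia-to-neuron ratios in the
3–7 band, wiring restricted to L1→L3, L3→L2, L2→L4) at desk scale; the
`scale` knob targets a structure radius of `7 * scale^(1/3)` lattice
units, about a thousand cells at `scale = 1`.

Design choices a maintainer should know, and why they are what they are:

* **Self-calibrating thresholds.** Every NSCF-derived threshold (division
  bound, boundary bound, apoptosis bound, the four intersecting layer
  intervals) is read off the quasi-steady radial profile of the
  stem-cell factor, computed at configuration time by relaxing an
  isolated field with exactly the run's own secretion/diffusion/decay
  rules. Thresholds therefore scale consistently with the target radius
  and with any change to the factor parameters.
* **Stem-cell onset delay.** The NSC stays quiescent until the NSCF
  concentration at the target radius has reached 90% of its steady value
  (measured during the same relaxation). Without this, early daughters
  read the still-growing gradient tail as "outside the structure" and
  trigger boundary behavior at the wrong radius.
* **A nearest-neighbor chain reaction.** The progenitor factor NPCF has
  emission radius 1 and both the chain-joining and the differentiation
  guards sense the cell's *own* coordinate. Joining the chain needs only
  a neighbor's halo (threshold 0.7); differentiating needs more (1.3),
  which in practice requires the cell's own secretion on top. The
  differentiation wave therefore relays strictly one shell at a time and
  commitment trails the relay — this is what makes the four layers
  appear sequentially from the outside in. (Wider emission radii or
  ball-summed sensing make the wave front effectively instantaneous at
  this scale; we tried both.)
* **Finite proliferative capacity.** NPC and GRPC divisions carry a
  `max_rounds` budget (6 and 3; daughters start fresh). At the structure
  boundary, apoptosis opens slots that neighbors would otherwise refill
  indefinitely — a divide/die churn that never settles. The budget lets
  that churn drain geometrically so runs reach true population
  quiescence. The mechanism default is unlimited rounds.
* **Glial amplification is subcritical.** The glial-restricted progenitor
  divides at a lower per-cycle rate (gate 0.42) than it differentiates
  (gate 0.6), for an expected ~2.4-fold expansion before the pool
  self-extinguishes; combined with the 0.32/0.68 neuron/glia lineage
  split this lands the glia-to-neuron ratio near 3. Subtype biases are
  NSCF-gated: type-1 astrocytes dominate centrally, type-2 astrocytes
  peripherally, oligodendrocytes spread evenly.
* **Wiring specificity is structural.** Each target layer emits its own
  guidance (AGF) and arrest (ACF) factors, and a growth cone's synapse
  partner is drawn only from its configured target type with a formed
  spine within the handshake radius — so wiring closure (only L1→L3,
  L3→L2, L2→L4 pairs) holds by construction, while connection *rates*
  remain emergent. After each synapse the cone reverses along the
  anti-gradient until guidance is lost, then searches again, which is
  what produces sequentially- and non-sequentially-repeated connections.
  Axon length is capped at six structure radii; blocked or
  guidance-starved cones simply wait (no retraction is modeled).
* The two variants differ only in the L3/L4 differentiation intervals
  (variant II trades L3 thickness for a larger, more peripheral L4) and
  in the guidance radii (the L2-neuron AGF radius is 1.5× larger in
  variant I, the L4-neuron AGF 1.4× larger, the L3-neuron AGF smaller by
  one unit).

The lattice is sized to the structure (`edge = 2*ceil(1.45R) + 3`, 25 at
scale 1) rather than to a fixed large cube; fields and occupancy scale
with `edge^3` and the organoid never approaches the walls.

### What the generator does and does not emulate

Runs at `scale = 1` exercise every mechanism and reproduce the
qualitative architecture — bounded S-shaped growth, a single surviving
stem cell, sequential layer onset, ordered radial medians, restricted
wiring with repeated-connection classes. They do not reproduce
tissue-scale statistics: hundreds of thousands of cells, millions of
synapses, near-saturated per-layer connection rates, or narrow
degree-distribution shapes all require structure radii far beyond desk
scale, because a layer that is one or two cells thick has large relative
stochastic fluctuations. Passing tests show the mechanisms and their
couplings behave correctly, not that the defaults match any particular
laboratory preparation. Chemical reactions between factors, cell
volumes/osmosis, neurite retraction and electrical activity are out of
scope.

## Analysis layer

`census()` reconstructs per-tick live counts per type (with cluster
grouping into multipotent progenitors, neuron/glial progenitors, neurons,
glia) and reconciles them exactly against cumulative births and deaths.
`radial_distribution()` normalizes Euclidean distances from the structure
center — by convention the initial stem cell's coordinate — by the
maximum over all neurons and bins them into 20 equal-width, left-closed
bins on [0, 1]; `distribution_entropy()` is the natural-log Shannon
entropy of those bins (0 for a point mass, log 20 for uniform). Entropy
base and bin count are stated here precisely because alternative choices
change the numbers. `connectivity_summary()` uses compartment-formed
denominators: the axon (dendrite) connection rate divides neurons with at
least one outgoing (incoming) connection by neurons that actually formed
the compartment, and the interneuron rate counts neurons with both,
among those with both compartments. `glia_neuron_ratio()` assigns each
layer the 10th–90th percentile band of its radial distances and counts
glia inside that band — the layer membership of a glial cell is not
otherwise defined.

## Problem sizes used in the tests

The suite validates diffusion against a dense convolution oracle on
grids up to 31³, pathfinding against breadth-first search on 100 random
15³ obstacle grids, stochastic gates over 10⁴ trials, and the full
organoid at scale 1 (lattice 25³, ~2,000 final objects, a few hundred
ticks to quiescence), with one shared organoid run reused across checks. These
sizes were chosen so that each property is measured well away from
trivial regimes while the whole suite stays quick to run.

## Known limitations

* Event logs at the default level record state changes only; full
  guard/gate tracing (level 1) is for small runs.
* The boundary leaves a shell of quiescent, never-differentiated
  progenitors outside the structure radius; they are inert but counted in
  the census, mirroring the residual progenitor populations the staged
  rules imply.
* A growth cone permanently enclosed by cell bodies never retracts; its
  pathway retires only when its length budget is exhausted.
* `run_until_quiescent()` defines quiescence on the cell population
  (census, births, deaths), not on connectivity: wiring may still be in
  progress when a run is declared quiescent, and long-horizon connection
  counts are better studied with a fixed tick budget.
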