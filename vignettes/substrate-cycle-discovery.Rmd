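---
title: "Discovering substrate cycles through retroactivity-based modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering substrate cycles through retroactivity-based modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcycles)
library(dplyr)
```

## The problem and the model

A substrate cycle is a set of reactions arranged in a loop that leaves its
main metabolites unchanged at steady state while transforming a cofactor —
classically, hydrolysing ATP. Formally we look for *cyclical elementary flux
modes* (EFMs) of a cofactor-stripped network: support-minimal flux vectors
$v$ with $S v = 0$ over the balanced metabolites, non-negative through
irreversible reactions, whose induced directed graph is a single strongly
connected component (SCC). Because a cyclical mode begins and ends on the
same balanced metabolites, every part of it lies inside whatever subnetwork
it is found in; a cyclical mode of a submodule is therefore also a mode of
every enclosing network. This containment property is what licenses a
divide-and-conquer search: enumerate exhaustively inside modules, where the
combinatorics are tractable, instead of once over the whole model.

The pipeline has five stages.

**Derivation.** Boundary (exchange) reactions touching extracellular
metabolites are removed first, then a *cofactor policy* is applied. The
policy is an explicit input, never inferred from node degree: whether a
species is a cofactor is context-dependent (a highly connected amino acid
can be a genuine substrate, while a compartment-specific NADP pool with
three reactions is still a cofactor). Two variants are derived: the EFM
network drops all policy cofactors (deliberately unbalancing them, so loops
over the remaining chemistry become candidate substrate cycles), while the
ShReD network keeps regulatory carriers such as ATP and NAD(H) — they
mediate retroactive couplings worth preserving in the partition — and drops
only inorganics (water, protons, phosphate, sulfate), whose shared
production and consumption is not a meaningful coupling.

**Retroactivity partition.** The network is abstracted to a reaction-centric
digraph: an edge $i \to j$ whenever some metabolite producible by $i$ is
consumable by $j$ (a reversible reaction counts as both producer and
consumer of everything it touches). The Shortest Retroactive Distance of a
pair, $\mathrm{ShReD}(i,j) = d(i \to j) + d(j \to i)$ in hops, is the length
of the shortest directed closed walk through both; it is finite exactly
within an SCC. Pairs with small ShReD are pulled into the same module by
recursive bisection of a similarity graph with weights $1/\mathrm{ShReD}$,
using the leading eigenvector of the modularity matrix followed by greedy
single-node refinement; a split is accepted only while its modularity
$Q = \sum_c [W_{in}(c)/W - (W_{deg}(c)/2W)^2]$ is positive, and a module
whose similarity graph is disconnected recurses into its connected
components. ShReD is recomputed inside each submodule, so cycles that leave
the module stop counting. A Newman comparator — identical machinery on the
unweighted symmetrized adjacency — isolates the effect of the metric.

**Enumeration.** Within each module (leaves first, then increasing height;
height is leaf-up, so enumeration exhausts the small terminal modules before
their larger ancestors) the module's stoichiometry columns are extracted,
dead-end metabolites pruned to a fixed point, reversible reactions split
into forward/reverse column pairs, and all elementary modes of the pointed
cone $\{x \ge 0 : Sx = 0\}$ enumerated by double description with the
combinatorial adjacency test. Each module runs under a cooperative
wall-clock budget (default 3600 s); a module that exceeds it is recorded as
skipped, all-or-nothing, and its ancestors are still attempted.

**Classification.** Each mode's bipartite digraph (reactions plus the
submodel metabolites they touch, edges oriented by the signs actually used)
is tested for being a single SCC with at least two reactions. An equivalent
reaction-projected test is implemented as a cross-check; the two coincide
because a true mode balances every submodel metabolite it touches.

**Reporting.** Each cyclical mode is multiplied back through the *full* base
stoichiometry. Species balanced in the submodel cancel exactly; the residue
is the cycle's net cofactor turnover, the quantity of biological interest.

## Numerical choices

All stoichiometry is exact: coefficients are rationals (numerator over
denominator), module matrices are cleared to integers row-wise, and the
double-description combination $v_p R_q - v_q R_p$ is reduced by its gcd at
every step. There is no zero tolerance anywhere in the enumeration —
support-minimality is combinatorially sensitive to what counts as zero, and
exactness removes that failure mode. Magnitudes are guarded at $2^{52}$
(doubles represent integers exactly to $2^{53}$); at the module sizes this
package targets the guard has never been approached.

Conventions that resolve genuine ties:

* **Sign canonicalization.** A fully reversible mode is a valid ray in both
  orientations; it is reported once, oriented so its smallest-id reaction
  carries positive flux. This avoids double-counting cycles in the cofactor
  summary while keeping the direction information.
* **Excluded trivia.** Forward+reverse split pairs of a single reversible
  reaction are suppressed by default (they are isomerization-style cycles of
  length 1); `include_isomerization = TRUE` restores them, flagged, since by
  the substrate-cycle definition they qualify. Reactions whose entire
  stoichiometry was pruned contribute no modes.
* **Determinism.** Node processing order is always sorted reaction id; the
  spectral sign is fixed by the first non-zero eigenvector entry; greedy
  refinement breaks ties toward the lowest id. Two runs with the same
  configuration produce byte-identical analysis artifacts (only wall-clock
  timings and the echoed output path differ).
* **Dead-end pruning** deletes the metabolite row but keeps the reaction, so
  an open pathway survives as a linear, non-cyclical mode rather than
  vanishing — which is exactly how the worked example's linear route
  coexists with its loop.

The modularity weight $1/d$ is the simplest strictly decreasing transform of
the distance; $e^{-d}$ is available as a configuration option, and nothing
downstream depends on the choice beyond the ordering principle (large ShReD
apart, small ShReD together).

## What the synthetic generator emulates

`generate_planted()` builds networks with known ground truth: closed chains
of fresh metabolites (the planted cycles, lengths ≥ 2) with cofactor couples
X/X\* attached at random so every cycle has a designed non-zero cofactor
net; linear decoy pathways with source and sink reactions, which survive
pruning as non-cyclical modes and exercise the classifier's specificity; and
acyclic bridge reactions between cycles, oriented low-to-high so no new
directed cycle can arise, which force the partitioner to cut somewhere. All
generated cofactors are placed in both policy sections, so the ShReD graph
reflects the carbon backbone alone.

These fixtures capture the *structural* signature of substrate cycling —
loops closed over balanced metabolites, unbalanced couples, decoys — but not
several features of real reconstructions: no shared metabolites between
cycles, no reversible tangles, no compartmental transport, no thermodynamic
information. Passing the planted-recovery suite therefore demonstrates that
the machinery finds exactly the loops that are there; it does not
demonstrate that every reported cycle in a real model is active *in vivo*,
which requires thermodynamic and experimental evidence and is explicitly out
of scope (cycles are reported as candidates). The shipped liver-reaction
excerpt (`inst/extdata/hepatonet_excerpt.tsv`) adds real chemistry at small
scale; the shipped cofactor policy
(`inst/extdata/cofactor_policy_synthetic.txt`) is the package's own
reconstruction of a typical compartmentalized list, not any published
model's curated file.

Problem sizes in the test and acceptance suites were chosen to exercise the
algorithms across regimes while staying desk-scale: random oracle systems
are kept to at most 10 split columns (the subset oracle is exponential by
construction, guarded at 20), planted fixtures use 3 cycles of lengths 2–5
with 1–2 bridges, and 50 seeded fixtures per recovery run. A genome-scale
run is a matter of budget, not of code path: the same functions apply, with
per-module timeouts doing the triage.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `time_budget` | 3600 s | per-module enumeration budget; timeouts are statuses, not errors |
| `metric` | `"shred"` | partition metric; `"newman"` is the connectivity comparator |
| `transform` | `"inverse"` | ShReD-to-weight transform (`1/d` or `exp(-d)`) |
| `boundary_tags` | `"x"` | compartment tags treated as extracellular |
| `cofactor policy` | reconstruction | which species to strip per analysis; supply your model's own list |
| `include_isomerization` | `FALSE` | report single-reaction both-direction cycles |

## Known limitations

* The recursive bisection is a heuristic on a nonconvex objective; a poor
  early split can strand the members of a genuine cycle in different
  branches, where it will only be found if an ancestor module completes
  enumeration. The metric comparison quantifies, not eliminates, this risk.
* ShReD is the shortest *closed walk* through a pair, computable by BFS; the
  shortest simple cycle through two prescribed nodes is NP-hard and is not
  what is implemented.
* Reported cycles are stoichiometric candidates. No Gibbs-energy screening,
  loop-law filtering, or flux-data weighting is performed.
* The SBML reader covers Level 2/3 species/reaction/stoichiometry/
  reversibility only — no gene rules, bounds, objectives, or annotations.

## A complete small run

```{r example}
gen <- generate_planted(planted_spec(n_cycles = 2, cycle_lengths = c(2, 4),
                                     n_bridge_edges = 1, seed = 7))
tf <- tempfile(fileext = ".tsv"); write_native_model(gen$model, tf)
pf <- tempfile(fileext = ".txt"); write_cofactor_policy(gen$policy, pf)
res <- run_pipeline(run_config(model_path = tf, policy_path = pf,
                               out_dir = tempfile(), seed = 7,
                               time_budget = 60))
glance(res$tree)
filter(res$cycles, cyclical)
res$summary
```
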