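---
title: "First-mover analysis of developmental connectome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-mover analysis of developmental connectome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firstmover)
```

## The model

During connectogenesis, neurons are born at stereotyped times and wire into an
expanding network. `firstmover` treats synapse formation as a sequential
leader–follower (Stackelberg) competition: a cell that enters the network
earlier constrains the options of cells that enter later. The observable
trace of this competition is the *birth-time difference* of each directed
chemical synapse,

\[
\Delta = t_{\mathrm{birth}}(\mathrm{pre}) - t_{\mathrm{birth}}(\mathrm{post}),
\]

negative when the presynaptic cell was born first. Decomposing each cell's
incident connections into pre-role and post-role, positive and negative
components yields five wiring strategies:

* **N–P coupling** — presynaptic partners born, on average, before
  postsynaptic partners (mean incident $\Delta < 0$);
* **XOR First Mover** — N–P, and *no* presynaptic partner of the cell born
  after it;
* **XOR Second Mover** — N–P, and *no* postsynaptic partner born before it;
* **XNOR** — both exclusions at once: every connection has the presynaptic
  cell born first and the postsynaptic cell born second;
* **P–N coupling** — the reverse tendency (mean incident $\Delta > 0$); a
  pure strategy that never co-occurs with the others.

The companion probabilistic object is a 2×2 *strategy profile* over
(role × birth order); its *conformity* is the probability mass on the
leader–follower heuristic (presynaptic partner born first plus postsynaptic
partner born second), 0.75 for the bundled reference profile. A payoff
matrix parameterises the utility of moving first, subsequently, or randomly
through an observed frequency `FREQ` and two milieu estimates `M` (molecular)
and `N` (neurophysiological).

## The decision procedure

`classify_strategy()` makes the verbal definitions operational:

1. **Base label.** The sign of the mean of $\Delta$ over *all* incident
   connections: negative → N–P, positive → P–N. The mean, not a majority
   count, is used; this is the "on average" reading, and it weighs large
   birth-time gaps more than marginal ones.
2. **Refinements.** Only for N–P cells, by universal quantification with
   zero tolerated violations (configurable via
   `first_mover_policy(exclusivity_tolerance =)`): XNOR first, which
   suppresses both XOR labels; otherwise XOR First, then XOR Second.
3. **Ties.** Bilateral pairs are born the same minute, so $\Delta = 0$ edges
   are common. A partner born at exactly the cell's birth time counts as
   neither born-first nor born-second: such edges are excluded from the
   universal tests but enter the mean as 0. A cell whose mean is exactly
   zero is a tie, resolved by policy (default: N–P, flagged, no refinement).

A consequence worth stating: both endpoints of a single old→new edge see the
same negative $\Delta$, so an isolated leader-ordered edge makes *both* cells
N–P (and vacuously XNOR). Strategies describe the ordering pattern of a
cell's connections, not a per-edge winner/loser split.

The alternative reading in which base labels are computed from row/column
means of the full pairwise matrix (rather than per-cell incident records) is
not taken: incident records are what a cell actually experiences, and the
policy object keeps the decision explicit and testable.

## Data model and conventions

* **Catalog** — one row per cell: name, birth time (minutes
  post-fertilization, validated to [0, 800], hatch), family, laterality.
  Families are nomenclature prefixes obtained by stripping trailing
  L/R/D/V characters (never below two characters; digits stop the strip, so
  IL2DL → IL2), with a small override table (URY → UR) for prefixes that
  suffix-stripping cannot decide.
* **Snapshots** — membership at time *t* includes births at exactly *t*
  (the 265-minute snapshot contains the cell born at 265). Stage
  differencing over (t1, t2] is the set difference of snapshots.
* **Burst histogram** — half-open bins `[lo, hi)` of width 8 minutes by
  default, anchored at the minimum observed time rounded down to a bin
  multiple; bursts are maximal runs of non-empty bins. With the reference
  windows the first two birth waves are contiguous in time, so the only
  silent window the histogram can detect is the 345–365-minute gap.
* **Synapse table** — directed chemical connections only (gap junctions are
  out of schema), each labelled transient/developmental/stable. Duplicate
  (pre, post) rows collapse to one connection by default because the
  analysis concerns cell–cell relationships, not synapse counts; a flag
  preserves multiplicity. Autapses are rejected unless explicitly allowed.
* **Overlap** — `shared / possible`, where *possible* is the size of the
  rarer strategy's cell set. This denominator reproduces the published
  8 / 4 / 10 denominators exactly.
* **Frequencies** — counted at the granularity of printed class names
  (IL2L/R is one entry), with the number of distinct assigned cells as
  denominator; 22/53 then reproduces 41.5%.
* **Payoff matrix** — the (subsequent, random) entry is implemented
  literally as `FREQ / 0.5`; a `subsequent_random = "product"` switch reads
  it as `FREQ * 0.5` in case the printed form is a typo. Only the
  presynaptic cell's payoffs are defined; the postsynaptic side is an open
  asymmetric-information gap and is not invented here. `M` and `N` have no
  estimation procedure and remain free parameters, with a warning when
  `FREQ * (M + N) > 1`.

## The growth simulator

`simulate_growth()` introduces cells in birth order. Each entering cell
initiates `max(1, Poisson(attach_rate))` edges to already-born cells, so no
edge ever touches a cell not yet born at its initiator's birth time. With
probability `conformity` an edge conforms to the initiator's planted
strategy — partners of a compatible strategy family are preferred and the
edge is directed old→new for N–P-family initiators, new→old for P–N — and
with probability `1 - conformity` the direction is reversed. Stability
classes are i.i.d. draws from `class_mix`. A plug-in `partner_kernel`
accepts alternative attachment rules (degree-preferential, fitness-weighted).

Noise-free simulation (`conformity = 1`, `exact = TRUE`) is required to make
classification invert generation exactly, and direction alone cannot achieve
that: any edge between an N–P-family cell and a P–N cell violates one
endpoint whichever way it points, and the three non-XNOR N–P labels are
*defined* by the presence of permitted counter-order connections. Exact mode
therefore (a) restricts conforming partners to compatible strategy families,
(b) adds the definitional *signature* edges — an outgoing-to-older
connection for plain N–P and XOR First cells, an incoming-from-younger one
for plain N–P and XOR Second — choosing the nearest-born partner whose own
label tolerates the counter-order edge, (c) guarantees each cell at least
one connection, (d) adds same-family repair edges until every mean delta has
its planted sign (repairs strictly improve both endpoints, so the loop
terminates), and (e) verifies every predicate, failing loudly rather than
returning an inexact dataset. Label draws that are infeasible at the
birth-order boundaries (a label requiring an older partner on the
first-born cell, and symmetrically) are repaired by swapping labels between
cells, preserving label counts.

## The synthetic generator

`generator_spec()` fixes the study conditions; its defaults are the stated
reference values wherever one exists, and one-time choices otherwise:

| parameter | default | source of the value |
|---|---|---|
| burst windows | 210–285, 285–345, 365–400 min | the three observed birth bursts; 345–365 silent |
| window weights | proportional to width (75/60/35) | no parametric law is given; uniform density across bursts |
| `pair_fraction` | 0.65 | ≈ 2/3 of terminally differentiated neurons are L/R pairs (98 pairs of ~302) |
| `planted_strategies` | published frequencies, normalised | the five labels are exclusive in the generator, so the N–P row weights plain N–P |
| `conformity` | 0.75 | the reference profile's conformity |
| `class_mix` | 0.43/0.14/0.43 | observed transient/developmental/stable proportions |
| `attach_rate` | 4 | gives mean total degree ≈ 8, a connectome-like density and the stratum used for recovery checks |

Birth times are drawn uniformly within a weight-selected window and floored
to whole minutes; paired cells share class, birth time and planted label.
Synthetic class names use letter stems chosen so that suffix stripping
recovers the planted family exactly.

What the generator does **not** emulate: per-animal variability across
reconstructions, per-timepoint synapse weights, spatial constraints, lineage
structure, and any correlation between strategy and family. Passing tests
therefore show that the pipeline's logic is correct and that the
classification inverts the generative model it states — not that the real
connectome satisfies that model.

## Verification strategy

* Classification is cross-checked against an independent brute-force
  evaluation of the definitional predicates, exhaustively over all directed
  edge sets on three cells with birth times in {0, 1, 2} and on hundreds of
  random networks of up to six cells.
* Planted-label recovery: at conformity 1 the full label set is recovered
  for every cell across 20 seeds at 60 cells; at conformity 0.75 the
  N–P/P–N base label is recovered for ≥ 90% of cells with at least 8
  incident records (fixed seed).
* The published desk-scale surface (frequencies 41.5/7.5/18.9/15.1/45.3%,
  overlaps 5/8, 2/4, 8/10, the 16-cell NSY-5 P–N split, the 87-neuron stage
  difference, conformity 0.75, the 53² = 2809-entry pairwise matrix) is
  recomputed from the bundled fixtures; `verify_fixtures()` produces the
  same table programmatically.
* Structural invariants (pairwise antisymmetry, CDF monotonicity, histogram
  conservation, byte-identical output under a fixed seed) run as
  property-style loops.

Problem sizes in the shipped tests and analysis scripts (60–120 cells for
recovery studies, ~1,300 cells once for the stability-mix check, 20 seeds
for round-trips) were chosen as the smallest sizes at which the stochastic
properties are stable.

## Known limitations

* The published stability-class percentages per strategy (e.g. the P–N row)
  do not sum to one and their denominator is undefined in the source; this
  package reports per-strategy class proportions that sum to one instead,
  and pins no check to those cells.
* The union of the printed strategy lists has 53 classes while the source
  text mentions 58 analysed cells; the fixtures carry the 53 printed names.
* The NSY-5 class list (13 classes in the methods text) is internally
  inconsistent with the stated 32-cell/28-pair count and with the
  discussion's P–N sublist (which includes AIY); both lists are shipped
  verbatim and not reconciled.
* Real 290-minute snapshot membership is not bundled; stage examples beyond
  the printed tables run on synthetic catalogs.
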