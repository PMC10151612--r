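---
title: "Assessing metabolic compatibility of host-endosymbiont pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing metabolic compatibility of host-endosymbiont pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endofba)
```

## The question and the model

Endosymbiosis between two prokaryotes — one cell living and growing inside
another — is vanishingly rare, yet one such event produced the
mitochondrion. One candidate barrier is *metabolic compatibility*: can two
metabolisms, drawn from the diversity of existing prokaryotes, actually
sustain each other when one is nested inside the other's cytoplasm?

`endofba` makes that question quantitative with constraint-based metabolic
modeling. A metabolism is a stoichiometric matrix $S$ (compounds $\times$
reactions) with flux bounds $\bar l \le \bar x \le \bar u$ and a biomass
reaction whose flux $x_\lambda$ proxies the growth rate. Instead of
explicit exchange pseudo-reactions, the environment enters as bounds on
compound derivatives: for compound $j$,

$$ a_j \;\le\; c_j' = \sum_k S_{jk} x_k \;\le\; b_j, $$

with $a_j = b_j = 0$ for internal (cytoplasmic/periplasmic) compounds
(steady state) and $a_j \le 0 \le b_j$ for extracellular ones; a negative
$a_j$ permits net uptake of $j$. Maximum growth in isolation is the linear
program $\max x_\lambda$ under these constraints. A metabolism is *viable*
when that optimum is at least $0.001$ — a biological cutoff three orders
of magnitude above the solver's feasibility tolerance ($10^{-9}$), and the
two are never conflated.

For an endosymbiosis, the endosymbiont's extracellular compartment *is*
the host's cytoplasm. The endosymbiont's matrix is partitioned by rows
into $S_E$ (compounds strictly inside the endosymbiont, kept balanced,
$S_E \bar y = 0$) and $S_{E\to H}$ (its extracellular rows re-mapped onto
the host's cytoplasmic rows). The pair grows in the *joint environment* —
the elementwise sum of the two ancestral environment bounds, in which each
ancestor is independently viable — by solving

$$ \max x_{\lambda_H} \quad \text{s.t.} \quad
\bar a_H + \bar a_E \le S_H \bar x + S_{E \to H} \bar y \le \bar b_H + \bar b_E,
\qquad S_E \bar y = 0, \qquad x_{\lambda_H} = y_{\lambda_E}, $$

plus the box bounds on both flux vectors. The equal-growth condition is a
hard equality: a nascent endosymbiosis has no division of labor, and both
partners must replicate at one rate for the lineage to persist. An
endosymbiont compound whose `base_id` exists nowhere in cytoplasmic form
is kept on a flagged fresh "orphan" row with $[0,0]$ bounds rather than
dropped, which makes the access-cause diagnosis below structural rather
than heuristic.

Two design choices deserve emphasis. First, the endosymbiont's ancestral
environment bounds are applied to the shared extracellular rows of the
joint system, never to host cytoplasm rows, which stay at steady state
while absorbing $S_{E\to H}\bar y$; this is the only reading under which
both ancestors remain independently viable in the joint environment.
Second, each pair system hosts a single endosymbiont copy (one $\bar y$
block).

## Diagnosing and repairing nonviable pairs

A pair can be nonviable in an environment where both ancestors grow, for
two non-exclusive structural reasons: (1) the host cannot transport a
compound the endosymbiont needs (or must dispose of) between its
extracellular and cytoplasmic compartments, and (2) the endosymbiont
requires direct contact with the environment for a compound that never
enters any cell.

`candidate_transport_compounds()` lists compounds that are available in
the joint environment in nonzero amount, exist in both extracellular and
cytoplasmic compartments somewhere in the shared namespace, and appear in
at least one endosymbiont reaction (we read "appears" as any compartment;
over-inclusion is harmless since repair viability is decided by the LP,
not the candidate list). `diagnose_nonviability()` stages the repair:
grant universal reversible host transport (symmetric bounds $\pm 1000$,
the collections' conventional "unbounded" magnitude) for all candidates;
if the pair is still dead, additionally grant the endosymbiont direct
environment access on its orphan rows. The transport flag marks pairs
where transports alone suffice *or* where an access-only rescue also
fails (so combined defects raise both flags, and the two causes need not
sum to 100%).

`minimal_transport_set()` estimates the minimum number of compounds whose
transport must be restored: starting from all candidates it greedily
attempts single removals in a seeded random order, keeping removals that
preserve viability. The result is provably irreducible (dropping any
member breaks viability) but not a guaranteed global minimum — greedy
set-cover-style elimination can overshoot — so the survey layer takes the
smallest cardinality over five seeded restarts, and the test suite checks
against exhaustive subset enumeration on instances small enough to
enumerate.

## Competition against the ancestors

Persistence is probed three ways, always in the same joint environment:

* **Survival under degradation** — every consumable compound is removed
  one at a time (`perturb()` zeroes only the uptake side: an absent
  nutrient cannot be eaten, but secretion stays possible), and the
  viability triple (pair, ancestral host, ancestral endosymbiont) is
  classified into eight exhaustive scenarios. Robustness is the fraction
  of perturbations survived.
* **Growth-rate comparison** — relative fitness
  $(g_{\text{focal}} - g_{\text{ref}})/g_{\text{ref}}$, classified
  faster/slower/equal at a relative tolerance of $10^{-6}$ and reported in
  both directions, since the natural denominator switches with the slower
  party.
* **Community growth** — host, endosymbiont and pair co-occur, their
  extracellular consumption pooled against a single set of environment
  bounds. Step 1 maximizes the summed biomass flux $z$; step 2 maximizes
  and minimizes each entity's biomass at fixed total $z$. Because LP
  optima need not be unique, an entity's growth counts as unique only when
  its step-2 range is within 10% of its maximum (entities with maximum 0
  count as unique; the 10% rule needs a denominator and we use the
  maximum); non-unique cases are excluded from community statistics and
  counted.

## Evolvability

A mutation relaxes one reaction's bounds by a factor $f = 1000$:
$l \mapsto -f\,|l|$, $u \mapsto f\,u$, then growth is recomputed and the
bounds restored. Relaxation can never lower an LP optimum, so mutations
are neutral or beneficial; "beneficial" requires a relative increase above
$10^{-6}$ so solver noise cannot create phantom benefits. For the rare
reaction with $l > 0$ the formula flips the lower bound's sign; such
reactions are flagged. Pairs are scanned separately over host and
endosymbiont reactions. Collections whose growth is environment-limited
show no beneficial mutations at all; `tighten_all_bounds()` (divide all
bounds by 100) moves them into the bound-limited regime first.

Beneficial-mutation counts of a pair and its matching ancestor are
compared with a paired two-sided Wilcoxon signed-rank test implemented
from its definition (midranks for ties, exact signed-rank null for
$n \le 25$ without ties, normal approximation with tie and continuity
correction otherwise); the per-batch viable fractions of different
collections are compared with a one-way ANOVA implemented from the
between/within sum-of-squares decomposition. Both are cross-checked
against `stats::wilcox.test()` and `stats::aov()` in the test suite — the
package's statistical surface is itself testable rather than delegated.

A structural point the scans expose: the nested system is *asymmetric*
even for identical partners. A host transport carries the demand of both
organisms, while the endosymbiont's own copy of the same transport carries
only its own; relaxing the former can be beneficial when relaxing the
latter is not. Symmetry of host- and endosymbiont-context scans holds only
when no transport bound binds.

## The linear-programming layer

No dedicated LP package ships with this R stack, so `solve_lp()` fronts
two interchangeable backends behind one contract (objective, constraint
matrix, row bounds, column bounds): a compiled bounded-variable two-phase
primal simplex written for exactly the shape flux-balance problems take
(equality rows over a box, heavy degeneracy — hence Dantzig pricing with a
Bland fallback against cycling), and a reformulation onto
`boot::simplex()` kept as an independent cross-check. The test suite
additionally validates the compiled backend against an external
interior-point implementation on randomized instances. All bounds must be
finite; flux-balance models use finite "effectively unbounded" magnitudes
throughout, which also guarantees the LP can never be unbounded. Solver
feasibility tolerance is $10^{-9}$; infeasible problems are reported as
growth 0 so the viability predicate is total.

## The synthetic generator: what it emulates, and what it does not

All tests and the acceptance analyses run on seeded synthetic collections
(`generate_collection()`, `generate_pair_with_defect()`,
`make_fixture()`), because the real curated model collections are
external downloads outside this package's scope. A generated model is a
guaranteed-viable backbone: each substrate is imported, converted through
a linear pathway of depth $d$, and feeds one biomass precursor; biomass
consumes one unit of each precursor, so maximum growth has the exact
closed form $\min(\text{availability}, \text{transport bound})$, which
every emitted model is verified against. Defaults: availability 10,
internal bounds 100, biomass bound 1000 (environment-limited, as in
collections limited by nutrient supply); setting the transport bound to 5
gives the bound-limited regime where mutations matter. Reaction bounds are
mildly position-scaled so a single constraint binds uniquely, as in real
networks with heterogeneous fluxes. Each model also carries two inert
environmental compounds — available but consumed by no reaction —
emulating the nutrient richness of curated environments; they are what
make "remove a compound and everyone survives" outcomes possible.
Substrates come from a small shared universe (size 3 for the survey
collections), so random pairs overlap partially and the fraction of
viable configurations lands mid-range rather than at 0 or 1. Engineered
defects mirror the two nonviability causes: a transport-deficient pair's
endosymbiont needs substrates the host cannot import (the recorded rescue
set), an access-deficient pair's endosymbiont consumes a compound with no
cytoplasmic form anywhere.

What passing these tests shows is that the machinery — restructuring,
nested LP, staged repair, two-step community program, mutation scans,
batched surveys — is correct on networks with known ground truth. What it
cannot show is anything about the biology of real genome-scale models:
synthetic pathways are short linear chains without cofactors, branching,
or realistic biomass composition; environments have a handful of
compounds, not hundreds; and the generator's viability fractions are a
property of its sampling design, not of prokaryote metabolism. Survey
quantities computed here (viable-configuration percentages, repair
statistics, competition and evolvability fractions) reproduce the *shape*
of the full-scale analyses at desk scale — e.g. pairs are almost always
slower than both ancestors, and beneficial mutations rarely lift a pair
past them — not the printed percentages from the real collections.

## Problem sizes and numerical choices

Survey defaults in this package's own analyses: collections of 40–60
models, 10 batches of 50–100 sampled pairs for viability, 4 × 25 viable
pairs for competition, 2 × 15 slower-than-both pairs for evolvability,
and 100 instances each for the repair and strip-and-repair checks —
sizes chosen so every generated LP stays under a few hundred variables
and the complete analysis runs in minutes on one core. Tie-breaks in the
simplex ratio test prefer the largest pivot magnitude; degenerate
iterations trigger Bland's rule after a stall threshold; basic solutions
are refreshed from the nonbasic bounds every 128 pivots to curb drift.
All randomness flows from one root seed through named substreams
(`substream_seed()`), so any single sampled pair can be re-run in
isolation and full surveys are byte-reproducible.

## Known limitations

* Single endosymbiont copy per host; no division of labor, regulation, or
  post-establishment adaptation structure.
* Repair adds reversible transports only; no gene-level gap-filling or
  cost-weighted repair.
* Mutations relax bounds of single reactions; no reaction gain/loss, no
  stoichiometric changes, no epistasis.
* The greedy minimal set is irreducible, not certified minimum (restarts
  mitigate; the enumeration oracle bounds the error on small instances).
* `maximize_growth()` requires finite bounds and therefore never reports
  an unbounded status; models imported from SBML with infinite bounds are
  clamped to $\pm 10^6$ at parse time.
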