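# endofba

Quantitative assessment of **metabolic compatibility in putative
prokaryote endosymbioses** with flux balance analysis (FBA).

Endosymbiosis — one prokaryote living and replicating inside another — is
extremely rare, yet one such event gave rise to eukaryotes. `endofba`
asks how much of that rarity simple metabolic incompatibility can
explain, for anyone working with genome-scale metabolic models: it
builds the nested two-organism linear program in which the
endosymbiont's extracellular compartment is the host's cytoplasm,
decides whether random pairs of metabolisms could grow as
host + endosymbiont, repairs the pairs that cannot, and competes and
mutates the pairs that can.

## The model

A metabolism is a stoichiometric matrix $S$ with flux bounds and a
biomass reaction (index $\lambda$); its environment is expressed as
bounds on compound derivatives, $\bar a \le S\bar x \le \bar b$, with
internal compounds at steady state and negative lower bounds permitting
uptake. Growth in isolation is $\max x_\lambda$ subject to those
constraints. For an endosymbiosis the endosymbiont matrix is partitioned
into internal rows ($S_E\,\bar y = 0$) and extracellular rows re-mapped
onto host cytoplasm rows ($S_{E\to H}$), and the pair solves

```
maximize x_λH   subject to
  a_H + a_E  ≤  S_H x + S_{E→H} y  ≤  b_H + b_E     (joint environment)
  S_E y = 0                                          (endosymbiont balance)
  l ≤ x, y ≤ u                                       (flux bounds)
  x_λH = y_λE                                        (equal growth)
```

Viability means growth ≥ 0.001. Around this core the package provides:
namespace harmonization and exchange-reaction externalization for SBML
(Level 3 + fbc) and a hand-writable TSV dialect; diagnosis of nonviable
pairs (missing host transport vs. missing environment access) and
irreducible minimal transport-repair sets; single-compound environmental
perturbation screens against the ancestral metabolisms; a two-step
shared-environment community LP with a 10% uniqueness rule;
bound-relaxation mutation scans (×1000) with sign-rank comparisons; and
seeded survey pipelines over model collections, all backed by a compiled
bounded-variable simplex solver and a self-validating synthetic network
generator.

## Worked example

```r
library(endofba)

# a transport-deficient pair: host grows on A, endosymbiont on N,
# and the host has no way to move N into its cytoplasm
fx <- make_fixture("TOY-PAIR-T")
maximize_growth(fx$host)                  # host alone
#> <flux_solution> status: optimal  objective: 10
maximize_pair_growth(fx$pair)             # nested pair: nonviable
#> <flux_solution> status: optimal  objective: 0
diagnose_nonviability(fx$pair)
#> <repair_diagnosis> transport: TRUE  access: FALSE  resolved: TRUE
minimal_transport_set(fx$pair, order_seed = 1)
#> [1] "N"
maximize_pair_growth(add_universal_transport(fx$pair, "N"))
#> <flux_solution> status: optimal  objective: 10
```

Granting the host a single N transporter restores growth — and the pair
then grows exactly as fast as either ancestor alone (10), because in this
toy environment the two partners do not compete for substrate. With a
binding transport bound they do compete; that fitness cost, its
robustness consequences, and the reach of single mutations are what the
survey layer measures:

```r
coll <- generate_collection(
  40, generator_params(universe_size = 3, transport_bound = 5), seed = 7)
sv <- run_viability_survey(coll, batch_design(n_batches = 10,
                                              batch_size = 100, seed = 7))
round(sv$viable_fraction, 3)              # fraction of viable configurations
#> [1] 0.406
round(sv$class_fractions, 3)              # neither / only-one / both viable
#>  neither only_one     both
#>    0.325    0.538    0.137
```

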