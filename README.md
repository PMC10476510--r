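# decbiogeo

Dispersal–extinction–cladogenesis (DEC) models with geology-encoded
dispersal constraints, for testing alternative geological histories with
phylogenies.

Historical biogeographers working on tectonically active regions — the
motivating system is the Papuan region and its hyperdiverse microhylid
frogs — need to ask not just *where* ancestral lineages lived, but *which
geological scenario* best explains how ranges evolved. `decbiogeo` provides
the full workflow in R:

* a DEC likelihood engine over discrete geographic ranges: anagenetic
  dispersal and local extinction along branches
  (`P(t) = exp(Qt)`, with expansion rates `d·Σ_{b∈R} m[b,a]` and per-area
  extinction rate `e`), and equiprobable vicariance/subset-sympatry range
  inheritance at speciation nodes;
* geological constraints as dispersal-multiplier matrices (connected pairs
  at 1, disallowed pairs at a 0.001 floor, optional distance weights) and as
  time-stratified "areas available" masks per epoch;
* maximum-likelihood fitting of `(d, e)` (every model has exactly two free
  parameters, so AIC = 4 − 2 logL), AIC ranking of competing hypotheses, and
  model-selection frequencies across posterior tree sets;
* marginal ancestral-range reconstruction, equal apportionment of multi-area
  probabilities to single areas, majority-rule node assignments, and
  tabulation of inferred dispersal events by source, destination and time
  bin;
* a builtin library of thirteen tectonic hypothesis models for the 13
  Papuan georegions (`builtin_hypotheses()`), from current connectivity
  through slow-and-steady accretion, mobile-belt and recent-emergence
  stratifications, to island-history and island-distance refinements;
* a stochastic DEC simulator (`simulate_tree()`, `simulate_dec_history()`,
  `recovery_experiment()`) so the entire pipeline is testable against known
  truth without any external data.

## Worked example

Simulate a study-scale clade (120 tips, 20 My root depth) under the
"Offshore with Nearest Mainland" hypothesis with dispersal rate 0.0094 and
extinction rate 0.021 events/My, rooted on the EPCT, then let five
hypotheses compete and reconstruct the dispersal history:

```r
library(decbiogeo)

hyp  <- builtin_hypotheses()
tree <- simulate_tree(120, seed = 7, depth = 20)
sim  <- simulate_dec_history(tree, hyp$j, dec_params(0.0094, 0.021),
                             root_range = "E", seed = 8)
tree <- ape::drop.tip(tree, sim$extinct_tips)
tips <- sim$tip_ranges[tree$tip.label]

res <- run_pipeline(tree, tips, models = hyp[c("a", "b", "g", "j", "DEC")],
                    condition = "survival")
res
```

```
DEC pipeline: best model 'j: Offshore w/ Nearest Mainland'

                            model neg2logL   dAIC        d        e   logL    AIC
1 j: Offshore w/ Nearest Mainland    248.9   0.00 0.009867 0.028033 -124.4  252.9
2                g: Owen Stanleys    267.5  18.57 0.006470 0.024699 -133.7  271.5
3               Unconstrained DEC    288.1  39.21 0.004044 0.015367 -144.0  292.1
4              b: Slow and Steady    384.4 135.53 0.031770 0.003755 -192.2  388.4
5         a: Current Connectivity    384.4 135.53 0.031766 0.003679 -192.2  388.4

Range transitions: 19 total (5 mainland-to-mainland, 8 mainland-to-island)
                  20-15 15-10 10-3 3-0
mainland_mainland     0     0    3   2
mainland_island       3     2    3   0
```

The generating hypothesis wins decisively (ΔAIC ≥ 18 to every rival), the
rate estimates sit near the simulating values (d̂ = 0.0099 vs 0.0094 true;
ê = 0.028 vs 0.021), and the transition table counts each inferred range
shift in the time bin of its ancestral node:

```r
res$transition_summary$source_pct_island[["E"]]
#> [1] 100   # all mainland-to-island dispersals originate from the EPCT
```

To analyse real data, read a time-calibrated Newick/Nexus tree with
`read_tree()` and a LAGRANGE-style presence matrix with `read_geography()`,
then call `run_pipeline()` with the full hypothesis library (the default).
`selection_frequency()` repeats the competition over a posterior tree set.

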