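---
title: "Testing geological hypotheses with DEC models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing geological hypotheses with DEC models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`decbiogeo` implements the dispersal-extinction-cladogenesis (DEC) model of
geographic range evolution on a rooted, binary, time-calibrated phylogeny.
A lineage's state is its *range*: the set of discrete areas it occupies, up
to a maximum range size (default 2). The null range ∅ represents total
extinction and is an absorbing state. Along branches, ranges evolve by a
continuous-time Markov process with instantaneous rate matrix **Q** whose
only nonzero off-diagonal entries are

* range expansion, R → R ∪ {a}: rate `d · Σ_{b ∈ R} m[b, a]`, where `d` is
  the base dispersal rate (events per area pair per My) and `m` is the
  dispersal-multiplier matrix; and
* range contraction, R → R ∖ {a}: rate `e` per occupied area (a single-area
  range contracts into ∅ at rate `e`).

Finite-time transition probabilities are `P(t) = exp(Qt)` (dense
scaling-and-squaring through the Matrix package; the likelihood engine uses
an eigendecomposition of each epoch's Q so that per-branch work is only
matrix–vector, with an automatic fall-back to `expm` if Q is numerically
defective). Extinction is a single shared per-area rate rather than
area-specific rates, so every model — however constrained — has exactly two
free parameters, and AIC = 4 − 2 logL throughout.

At speciation nodes the ancestral range is partitioned under the classic DEC
cladogenesis distribution: a single-area ancestor is copied to both
daughters; a wider ancestor undergoes vicariance or subset sympatry, with
ordered daughter pairs enumerated and weighted equally (six events of
probability 1/6 for a two-area ancestor). Founder-event ("jump") transitions
are deliberately not modelled: on single-area-endemic data DEC+J fits
degenerate to zero dispersal and extinction with all change crammed into
jumps, which is a pathology rather than an estimate, so the model family is
excluded.

The likelihood is computed by Felsenstein pruning, integrating over all
internal range assignments and cladogenetic events; the root likelihood sums
the root vector over non-null ranges (the classic DEC convention; a
uniform-prior average is available via `root = "uniform"`). An optional
survival conditioning (`condition = "survival"`) divides by the probability
that no tip is extinct; see *Recovery experiments* for when that matters.

## Encoding geology

Two mechanisms encode geological scenarios:

* **Dispersal multipliers.** Connected area pairs carry multiplier 1;
  disallowed pairs carry a small positive floor (0.001 by default) rather
  than exact zero, keeping every model identifiable. Distance classes can
  override with intermediate weights (the island-distance model uses 0.1 for
  near islands and 0.001 for far ones, with free movement within
  archipelagos). Matrices are symmetric with unit diagonal.
* **Time-stratified area availability.** The timespan is cut into contiguous
  epochs, each with a mask of areas available for occupancy; a single
  multiplier matrix is shared across epochs. Expansion into an unavailable
  area has rate exactly 0 — availability is a hard constraint, distinct from
  multiplier softening — while ranges already containing an unavailable area
  may still contract, so lineages stranded by a vanishing area can go
  locally extinct. Branches crossing epoch boundaries are split at the
  boundary ages and their per-segment transition matrices chained oldest to
  youngest.

## The Papuan hypothesis library

`builtin_hypotheses()` constructs thirteen competing models over the 13
Papuan georegions (five mainland terranes V, C, F, A, E; seven offshore
islands Y, G, B, W, M, S, R; Southeast Asia N). The published displays use
an 11-region layout (Normanby and Fergusson collapsed into "D", Southeast
Asia omitted); `display_multipliers()` reproduces that layout. Where the
published record is pictorial or internally inconsistent the library ships
documented interpretations, all overridable through `hypothesis_spec()`:

* The current-connectivity pairwise matrix is taken verbatim from its
  published numeric display. The slow-and-steady model (b) shares that
  connection matrix — the published island-hypothesis matrix, which is
  stated to layer on b, carries the identical mainland block — and expresses
  its geological content through stratification: the Vogelkop Peninsula is
  unavailable before its mid-Miocene docking (boundary 15 Ma).
* Mobile Belt (c): the Accreted Terranes, assembled offshore in the Late
  Oligocene and docking 15–11 Ma, are unavailable before 11 Ma.
* Recent Emergence (d): before 5 Ma only the Fold Belt's high mountains and
  the approaching EPCT (plus the non-mainland areas) are available.
* Normanby and Fergusson inherit the collapsed "D" pattern and are mutually
  connected at 1; Southeast Asia sits at the floor in every hypothesis
  (its connections are never stated).
* Island hypotheses e–l layer archipelago blocks, EPCT/Accreted pairwise
  connections, or distance weights on b, following their verbal
  descriptions; the oldest epoch of every stratification opens at infinity
  so trees of any root age are covered.

Epoch boundaries (15, 11, 5 Ma) are interpretations of prose, not printed
numbers, and are the single most uncertain element of the library.

## Fitting and model competition

`fit_dec()` maximizes the log-likelihood over (d, e) with Nelder-Mead on
log-scaled rates inside the box [1e−9, 10]: four fixed starting points
log-spaced in each rate are screened by their initial likelihood and the
best two polished (relative tolerance 1e−10, i.e. ~1e−8 on logL). The
multi-start is deterministic, so fits are exactly reproducible. The rate
surface of DEC in (d, e) is smooth and in practice unimodal; the screened
second start guards against the occasional flat ridge at the box edge.
`compare_models()` ranks fits by AIC (ties broken by model name) and
`selection_frequency()` repeats the competition across a set of trees,
splitting exact ties equally.

## Ancestral ranges and dispersal counts

`reconstruct_ancestral_ranges()` computes marginal posteriors per node by
the standard two-pass algorithm (tipward conditional likelihoods from the
pruning pass, rootward partials propagated down through the cladogenetic
event distribution and transposed branch propagators). Marginal — rather
than joint — reconstruction matches the output style of the established DEC
software; a max-product joint mode is available as a sensitivity check.
Because the study clades are single-area endemics, multi-area posteriors are
apportioned equally among member areas (a two-area range with probability
0.10 contributes 0.05 to each), and each node is assigned its majority-rule
area — the argmax of the apportioned vector, ties broken by area order with
a warning.

`count_transitions()` then records, for every parent→child edge whose
assigned areas differ, one transition in the time bin containing the parent
node's age (the shift is attributed to the ancestral node along whose
descendant branch it occurred; edges into tips are counted). Bins are
half-open [older, younger) with the default breaks {20, 15, 10, 3, 0} Ma;
ages older than the oldest break go to an overflow bin with a warning.
`summarize_transitions()` classifies the marginals by area category
(mainland-terrane vs island) and reports per-source percentages rounded to
the nearest integer.

## The synthetic-data generator and recovery experiments

`simulate_tree()` draws a pure-birth tree conditioned on the tip count and
rescales it to a fixed root depth — 20 My by default, the approximate age of
the Papuan study clade, with 218 tips and the 13 georegions as the default
study-scale configuration. `simulate_dec_history()` simulates the full DEC
process: anagenetic events by competing exponentials from the
epoch-appropriate Q row (boundary ages handled by censoring), cladogenetic
events drawn from the event distribution, the null range absorbing. The
default rate magnitudes for experiments, d = 0.0094 and e = 0.021 events/My,
are the study's best-fit estimates. A mandatory seed makes every history
exactly reproducible; replicate seeds are derived deterministically from the
experiment seed.

What the generator emulates: study-scale tree shape, root depth,
single-area-dominated tip ranges, constraint-structured dispersal, lineage
extinction. What it does not: phylogenetic uncertainty (the tree is taken as
true), diversification–range interactions (extinct DEC lineages do not
remove tree branches; the tree is pure-birth), geographic sampling bias, and
within-area population processes. Passing recovery tests therefore validate
the inference machinery, not the realism of any particular geological
scenario.

`recovery_experiment()` simulates, drops extinct (null-range) tips, refits,
and summarizes. Dropping extinct tips conditions the data on survival, so
the experiment fits with the survival-conditioned likelihood by default: the
unconditioned fit on such data systematically drives the extinction rate to
the lower bound, because unobserved lineage loss is penalized while
cladogenetic vicariance explains range contraction for free. Even
conditioned, ê is the weakly identified parameter and inherits a mild upward
bias from pruning: nodes whose sister subtree died are removed, so
cladogenetic subset-sympatry contractions that actually happened there must
be absorbed anagenetically by e. Dispersal-rate recovery is accurate (median
relative error well under 30% at study scale); extinction-rate recovery is
honest to within about a factor of two. Problem sizes used by the shipped
experiments — 20 replicates of 218-tip trees over 13 areas — were chosen as
the smallest scale at which these behaviours are stable.

## Numerical choices and degenerate inputs

* Rescaling of conditional vectors at every node guards against underflow on
  large trees; log scalers accumulate exactly.
* The eigendecomposition propagator is verified by reconstructing Q to
  1e−8·max(1, max|Q|); failure falls back to scaling-and-squaring per
  segment. Small negative entries from complex round-off are clipped to 0.
* Ultrametricity is checked to 1e−3 of root height; violations warn rather
  than fail, since published trees carry rounding. The present is the
  maximum tip depth.
* Zero-probability data (e.g. an observed area whose expansion rate is
  exactly 0 in every epoch) return −Inf cleanly; the optimizer treats such
  points as hard rejections.
* Ties: AIC ties split selection credit equally and are broken by model name
  in rankings; majority-rule ties go to the lowest area index with a
  warning.

## Known limitations

* The extinction rate is weakly identified in DEC; its estimates should be
  read as order-of-magnitude.
* The cladogenesis model is fixed (equiprobable vicariance + subset
  sympatry); no weighting parameter and no founder events, by design.
* Epoch boundaries of the builtin stratified hypotheses are interpretive
  defaults; analyses that hinge on them should vary them via
  `hypothesis_spec()`.
* Reproducing the published Papuan fits requires the study's deposited tree
  and geography, which are not distributed with the package; `run_pipeline()`
  executes that workflow end-to-end once the files are supplied.
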