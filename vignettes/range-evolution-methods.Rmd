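---
title: "Modelling geographic range evolution: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling geographic range evolution: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decrates)
```

## The model

A lineage's geographic range is a non-empty subset of a fixed set of areas
(six Neotropical bioregions in the package's reference scenario: A North
America, B Caribbean-Mesoamerica, C Amazonia, D Dry diagonal, E Andes,
F Atlantic Forest). Ranges evolve by two kinds of events.

**Anagenetic events** happen along branches and follow a continuous-time
Markov chain on the power set of areas. Range expansion adds one area `b`
to a range `G` at rate

$$q_{G \to G \cup \{b\}} \;=\; d \sum_{a \in G} m^{(s)}_{ab},$$

where `d` is the base dispersal rate (events per lineage-Myr) and
`m^(s)` is the dispersal multiplier matrix of the time slice `s` containing
the moment of the event. Range contraction removes one occupied area at
rate `e` per area; a single-area range contracts into the *null range*, an
absorbing state that is carried internally (state 1 of every rate matrix)
but never observed at a tip.

**Cladogenetic events** happen at nodes and draw the two daughter ranges
from the ancestor's range `G` with equal weights over the allowed set:

* `DEC`: a single-area ancestor is copied; a wider ancestor undergoes
  subset sympatry (`{a}` vs `G`) or strict vicariance (`{a}` vs
  `G \ {a}`), with both left/right assignments counted as distinct events
  (a two-area ancestor therefore has six events of weight 1/6).
* `DIVALIKE`: copy for single areas; otherwise any vicariant bipartition
  of `G` into two disjoint non-empty parts.
* `BAYAREALIKE`: the range is copied unchanged, whatever its size.

The founder-event weight `j` is fixed at zero: the three families above are
the supported models, and the interface rejects `j > 0` rather than
silently ignoring it.

The likelihood is computed by Felsenstein pruning over the range state
space: tip conditionals are indicators of the observed ranges, node
conditionals combine the daughters through the cladogenetic event
distribution, and branch propagation multiplies slice-specific transition
matrices `exp(Q^(s) t)` segment by segment wherever a branch crosses an
epoch boundary. At the root the likelihood averages the conditionals under
a **flat prior over non-empty ranges**. That convention matters when
comparing absolute log-likelihood values with other software, which may
weight the root by the cladogenesis-conditional state frequencies; all
within-package model comparisons are unaffected because every model uses
the same prior.

## Time stratification

An epoch model is a descending vector of slice boundaries ending at 0 (Ma
before the present) plus one multiplier matrix per slice, e.g. boundaries
`c(11, 7, 0)` for an 11–7 Ma slice and a 7–0 Ma slice. The packaged
reference matrix (`inst/extdata/dispersal_multipliers.txt`) encodes
adjacency of the six bioregions at two coarse palaeogeographic stages:
contiguous regions 0.5, regions separated by one region or by water 0.1,
regions separated by more 0.01, and a 0.7 corridor between the Mesoamerican
lowlands and the still-undeveloped northern Andes in the older slice.
Ages above the oldest boundary are treated as belonging to the oldest
slice, so a root marginally older than the top boundary does not invalidate
an analysis.

## Fitting

`fit_range_model()` estimates `(d, e)` by bounded maximum likelihood:
L-BFGS-B on `(log d, log e)` from the fixed start `d = e = 0.01` with box
`[1e-9, 5]` per parameter on the natural scale. The surface is smooth and
two-dimensional, so no multi-start is used and refits are exactly
reproducible. `model_selection()` assembles the usual comparison table with
`AIC = 2k − 2 lnL`, `AICc = AIC + 2k(k+1)/(n − k − 1)` with `n` equal to
the number of tips, and Akaike weights `exp(−Δ/2)` normalized within the
compared set. The tip count is a convention, not a law; AICc differences
between models with equal `k` are insensitive to it.

A practical note on `e`: under DEC-style subset sympatry, narrow daughter
ranges appear at nodes without any anagenetic contraction, so the
likelihood often prefers `ê ≈ 0` even when ranges do contract — a known
structural property of this model family, visible in most published DEC
fits. The package's parameter-recovery experiment (below) therefore uses
the copy-only cladogenesis family, under which both rates are identifiable.

## Ancestral ranges and stochastic mapping

`ancestral_ranges()` runs the standard two-pass algorithm to obtain, at
every node, the marginal posterior over non-empty ranges immediately
before cladogenesis. Two single-area summaries are emitted, because a
"most probable area" can reasonably mean either: the MAP range (ties broken
by the deterministic state order — size first, then lexicographic) and the
MAP area (argmax over areas of the summed probability of ranges containing
the area). The MAP range is the default plotted value.

`stochastic_map()` samples full histories conditional on the tips: the
root state from its joint posterior, each node's cladogenetic event
conditional on the parent state and the daughters' partial likelihoods,
and each branch path endpoint-conditioned by **uniformization**: with
`μ = max |Q_ii|` and `R = I + Q/μ`, the number of uniformized jumps is
drawn from its exact conditional distribution and the jump states from the
discrete bridge, virtual (self-) jumps being discarded. Branches crossing
epoch boundaries first draw the state at each boundary from the
conditioned segment products. A forward-rejection fallback (capped at 1000
retries) covers numerically degenerate segments; in practice it is never
reached on well-conditioned matrices. Sampled node-state frequencies are
tested against the analytic marginals at 10,000 samples.

## Event counting and rates through time

Each history is reduced to per-time-bin counts: an expansion gaining area
`b` from prior range `G` is one dispersal into `b` with source mass `1/|G|`
attributed to each occupied area (this fractional rule is what keeps
emigration and immigration totals exactly conserved, `Σ_X df_X = Σ_Y
dt_Y`, in every bin of every history); contractions are tallied
separately; and a cladogenetic event counts as in situ speciation in every
area occupied by the ancestor and retained by at least one daughter —
a deliberately permissive, easily testable rule (a copy counts in all its
areas, a vicariance counts in every area that survives on either side).

Rates divide the counts by exposure:

* in situ speciation rate `λ_X = s_X / L_X(t₀)`, with `L_X(t₀)` the number
  of lineages occupying `X` at the **old edge** of the bin;
* colonization `c_{X→Y} = d_{X→Y} / Br`, emigration `E_X = df_X / Br`,
  immigration `I_X = dt_X / Br`, with `Br` the total branch length of all
  lineages in the bin (lineage-Myr). An area-restricted denominator is
  available behind `area_restricted_br = TRUE` for sensitivity analyses.

The default bin width is 0.5 Myr, purely a resolution choice; every
function takes `bin_width`. Rates with a zero denominator are missing, and
cross-replicate medians and quartiles (0.25/0.75) are computed over the
non-missing replicates. `relay_summary()` reports, per bin, the area with
the maximal median λ, E and I, and the contiguous intervals over which
each area holds each maximum — the "relay" phases; ties are flagged
explicitly rather than broken silently.

## Pseudoreplicate trees

Dating uncertainty is emulated by `jitter_node_ages()`: each internal node
age is multiplied by a lognormal factor with coefficient of variation
`cv`, then a single root-to-tip sweep clamps every child strictly below
its parent, leaving tips at the present. Missing taxa are emulated by
`graft_missing_tips()`: the attachment point is drawn uniformly over the
total branch length of the attachment clade (a length-weighted branch,
then a uniform age along it), and the new tip's pendant branch reaches the
present. Grafted taxa must be given ranges by the user — the package does
not invent distribution data. At full scale the replicate design is 1000
trees × 100 mappings (100,000 histories); tests and examples run at
20 × 20 or below, which already stabilizes the median rate curves.

## The forward simulator

`simulate_chronogram()` draws a constant-rate birth–death tree conditioned
on the tip count (via `ape::rphylo`) and rescales it to the target crown
age; only the birth/death ratio shapes the node-depth profile after
rescaling. Defaults follow the reference scenario: 134 tips, crown age
8.6 Ma, six areas, two slices at 11 and 7 Ma, a Caribbean-Mesoamerican
root range, `d = 0.16` (the constrained-DEC scale of the reference
analysis) and a small `e = 0.01`.

`simulate_ranges()` runs the range process forward: a cladogenetic draw at
every node and the slice-specific CTMC along every branch. The null range
needs a policy, because observable data cannot contain empty ranges. The
default, `null_range = "forbid"`, removes last-area loss from the
generator — the survivorship construction standard for producing datasets
that look like observed ones. The alternative `"resimulate"` redraws whole
realizations until none hits the null range; at realistic extirpation
rates on large trees this conditions on a vanishingly rare event (with 300
tips and `e = 0.01`, essentially every realization has at least one
last-area loss), so it is practical only for small or low-`e` settings.
`"keep"` retains extinct-in-place lineages, flagged, for stress testing.
Truth logs use the same schema as stochastic-mapping output, so the whole
counting and rate machinery runs unchanged on simulated truth.

## What the synthetic test bed does and does not show

The generator emulates the study conditions (tip count, crown age, area
system, two-slice multipliers) but not several features of real data:
non-random taxon sampling, phylogenetic and dating error in the input tree
(only emulated parametrically by the jitter), range-assessment error in
the geography table, and diversification that depends on the occupied
areas. Green tests therefore certify the *implementation* — exact
likelihoods against enumeration, exact conservation laws, sampling
consistency, parameter recovery under the model — not the adequacy of the
DEC family for any particular empirical system.

Problem sizes used by the packaged validation suite, chosen to keep a full
run on one core in minutes: brute-force enumeration on ≤4 tips × ≤3 areas;
mapping-vs-marginals at 10,000 samples on a 6-tip tree; parameter recovery
on 100 datasets of 300 tips with 3 areas under copy-only cladogenesis at
truth `(d, e) = (0.02, 0.01)` (median estimates land within ±50% of
truth); and a two-phase relay scenario (source switch at 4 Ma, 1-Myr bins,
120 tips) recovered within one bin in ≥90% of 30 replicates.

## Numerical choices

* Transition matrices use an eigendecomposition fast path (one
  factorization per slice per likelihood evaluation, two dense products
  per branch), falling back to `Matrix::expm` scaling-and-squaring when
  the eigenbasis is ill-conditioned; results agree to 1e-8 in tests.
  Dense matrices throughout — the six-area space is only 64 states.
* Partial likelihoods are rescaled at every node (log-scale accumulator),
  so 300-tip trees are far from underflow.
* Ultrametricity is enforced within 1e-6 Myr; sub-tolerance deviations
  from Newick round-trips are repaired by extending terminal branches.
* MAP ties break deterministically by state order; relay ties are
  reported, not broken.
* Impossible data (e.g. conflicting tips under a copy-only model with
  `d = e = 0`) yield `lnL = −Inf`, reported distinctly rather than as an
  optimizer error.

## Known limitations

Founder-event (`+J`) speciation is deliberately out of scope. The root
prior convention shifts absolute log-likelihoods relative to other
implementations. `e` is weakly identified under DEC-style cladogenesis
(see above). The BSM event counts inherit whatever bias the fitted model
has; running the mapping under the unconstrained model (the default in
`run_pipeline()`) avoids imprinting the multiplier matrix on the counts
but smears sharp regime changes, so changeover ages estimated from mapped
histories are conservative relative to truth-log estimates.
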