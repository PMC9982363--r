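---
title: "Models and methods behind methanotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methanotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanotrace)
```

`methanotrace` bundles the computational machinery needed to ask how
methanogenesis and the Archaea co-evolved: reconciling gene trees of
methanogenesis enzymes (the F430 biosynthesis pathway CfbABCDE, the
methyl-transfer complex MtrAH, the methyl-S-CoM reductase family
McrBDCGA) against a rooted archaeal species tree; rooting those gene
trees by several independent methods and a consensus rule; predicting
intracellular metabolite concentrations for alternative methanogenesis
routes by quasi-equilibrium thermodynamics; scoring genomes for
biosynthetic self-sufficiency; and estimating ancestral growth
temperatures from reconstructed 16S rRNA base composition. Every stage
has a seeded synthetic-data generator, so the whole pipeline is testable
against known ground truth without downloading anything.

This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions that were genuinely open.

## Trees

Trees are `ape::phylo` objects. A tree is *rooted* when its top-level
node has exactly two children; unrooted trees carry the usual
trifurcating anchor. `parse_newick()` enforces unique non-empty leaf
labels and non-negative branch lengths; absent lengths are filled with a
default of 1.0 (with a warning) because every downstream method needs
lengths, and the trees this package targets always carry them.
Multifurcations are resolved left-to-right with zero-length branches by
default (reconciliation requires binary input); a `"reject"` policy is
available when silent resolution would be inappropriate. Internal-node
labels are treated as opaque support values and preserved.

Rooting positions are expressed as an edge (identified by its child
node) plus a fraction in `[0, 1]` measured from the child end.
`reroot_at()` is isometric — no leaf-pair path length changes — and a
former root left with a single child is spliced out. Because subunit
trees of a protein complex differ in taxon sampling, root branches are
compared across trees as *leaf bipartitions restricted to the shared
leaf set* (`same_bipartition()`), never as node identities.

## Rooting methods and the consensus rule

Four methods produce `rooting_candidate`s:

* **Outgroup** (`outgroup_root()`): the root is placed mid-edge on the
  branch separating a user-stated outgroup clade; failure to be
  monophyletic under any rooting is an error naming the minimal set of
  conflicting leaves. Outgroup evidence, when available, is the
  prioritized method.
* **Midpoint** (`midpoint_root()`): midpoint of the longest leaf-leaf
  path; the score is half the tree diameter.
* **MAD** (`mad_root()`): for each branch, the root position minimizing
  the root-mean-square *relative ancestor deviation* over leaf pairs,
  `|2 d(a,i)/d(i,j) - 1|` for pair `(i, j)` with induced ancestor `a`.
  For pairs on the same side of the candidate branch the deviation is
  independent of the root position; for pairs spanning it the deviation
  is linear in the position, so the squared objective is quadratic and
  the per-branch optimum has a closed form, which the test suite
  validates against a 1000-point grid search built from the definitional
  deviations. Ties across branches break deterministically on the
  lexicographically smallest leaf bipartition, purely for
  reproducibility. Deviations use path lengths exactly as stored; no
  rate smoothing is attempted.
* **Reconciliation** (`reconciliation_root()`): every rooting of the
  gene tree is scored by its minimum DTL cost (below); all co-optima are
  returned.

`consensus_root()` groups candidates by bipartition and accepts a root
branch only when **at least two methods** and a **strict majority of
subunits** support it. Subunits for which a method produced no result
are counted only where the method ran — the counting rule the package
commits to, since the alternative (counting failures as dissent) would
make the majority threshold depend on unrelated method failures. When an
outgroup candidate exists its branch is always reported first,
reflecting the priority of outgroup evidence over score-based methods.

## DTL reconciliation

`reconcile()` implements undated duplication–transfer–loss parsimony for
a rooted binary gene tree against a rooted binary species tree, with
speciation free and costs `D`, `T`, `L` for duplication, transfer, and
loss. The dynamic program fills `c(g, s)` — the minimum cost of the gene
subtree at `g` mapped to species node `s` — using the auxiliary
quantities `in(g, s)` (best cost allowing a chain of losses descending
from `s`) and `out(g, s)` (best cost at any species node incomparable to
`s`, the legal transfer recipients in the undated model). Transfers land
directly on their recipient, so no losses accrue on the recipient side;
donor and recipient must be incomparable, and a transfer into an
ancestor of the donor is impossible by construction. Losses are counted,
not placed on named species branches: counts are all that cost
computation and event summaries need.

Three numerical commitments matter:

* **Exact cost arithmetic.** Costs are small rationals; they are scaled
  by their common denominator to integers, and the whole DP runs on that
  integer scale, so "minimum" and "co-optimal" are exact notions, never
  floating-point comparisons.
* **Co-optimal sampling.** When several events or loss chains achieve
  the optimum at a node, one is drawn uniformly *at that decision
  point* with a seeded generator. This is the same local-uniform
  behaviour aggregation tools in this field rely on; it is not a
  globally uniform draw over all co-optimal histories (which would
  require counting them), and the event-support semantics below are
  defined relative to it. Transfer recipients are drawn uniformly among
  the optimal recipients after the event type is chosen.
* **The brute-force oracle.** `brute_force_reconcile()` enumerates every
  mapping of internal gene nodes onto species nodes and prices the
  cheapest event labelling of each, independently of the DP. It refuses
  instances above 8 leaves; the suite runs hundreds of random ≤ 6-leaf
  instances through both routes and requires exact agreement.

`opt_root_dtl()` evaluates all `2n - 3` rootings and returns the full
cost table plus every co-optimal root branch — deliberately a set, since
transfer-cost calibration is about whether a *target* rooting is among
the co-optima. `optimize_transfer_cost()` sweeps an ascending transfer
cost grid and reports the smallest value whose co-optimal rootings
contain the target branch (or reports none, without raising). The spec
of the sweep leaves the duplication cost open; the package defaults to
`D = T/2`, the midpoint of the `{T/4, T/2, 3T/4}` sweep used downstream,
so calibration and aggregation probe the same cost neighbourhood.

`aggregate_reconciliations()` reruns the reconciliation `n_runs` times
with `D` drawn from `{T/4, T/2, 3T/4}` and per-run seeds, and reports
per-node event supports as run fractions. The run budget is interpreted
as a *total*, split as evenly as possible with the remainder assigned to
the smallest `D` (the most transfer-friendly setting); with 100 runs
that is 34/33/33. Supports per node sum to one by construction.

## Quasi-equilibrium pathway thermodynamics

The solver (`solve_equilibrium()`) treats a methanogenesis route as an
ordered list of reactions with standard transformed Gibbs energies
ΔG°′ (kJ/mol, pH 7, 1 M / 1 atm standard states, water activity 1,
protons absorbed into ΔG°′), a set of fixed boundary species (gases as
partial pressures in atm, aqueous species in mM), and cofactor pools
whose member concentrations must sum to a fixed total. Each reaction has
a mode: *equilibrium* (realized ΔG = 0) or *fixed* (realized ΔG equal to
a stated value — negative for energy conservation/dissipation, positive
for energy investment) — and names the single species it adjusts. That
designation is explicit in the scenario config rather than inferred,
because which step dissipates energy is a modelling statement about the
organism, not something an algorithm should guess.

One sweep solves each reaction's single-unknown equation in closed form
(`ΔG = ΔG°′ + RT ln Q` solved for the adjustable activity), then
rescales every pool to its total. Redox couples tied to H₂ (the
F420/F420H₂ pair) are ordinary two-member pools pinned by an equilibrium
reaction with H₂; pool rescaling multiplies both members by the same
factor, preserving the ratio, so the redox constraint survives
conservation and the Gauss–Seidel-like iteration converges in a handful
of sweeps for chain-structured pathways. Convergence requires every pool
sum within a relative `tol` (default 1e-6, iteration cap 10,000, optional
geometric damping) *and* every reaction within `tol·RT` of its target
ΔG. Structural over- or under-determination (a species adjusted twice; a
free species neither adjusted nor pooled) is detected and warned about
at model construction. The suite additionally checks the iterative fixed
point against a simultaneous nonlinear solve of all constraints for
small models, pool conservation to 1e-9, monotonicity of reduced-carrier
concentrations in the H₂ partial pressure, and exact scale covariance of
ΔG°′ = 0 toy models.

Two scenario configs ship under `inst/extdata/thermo/`. They are *data,
not code*: the ΔG°′ values are the standard compiled per-step energies
for the archaeal methyl branch (formyl-MFR dehydrogenase +16.0,
formyl transferase −4.4, cyclohydrolase −4.6, F420-dependent
dehydrogenase +6.5, reductase −5.2, F420 hydrogenation −11.1,
methyl transfer to CoM −30.0, methanol:CoM methyl transfer −27.5,
terminal reductase −45.0 kJ/mol), and the boundary conditions encode one
explicit habitat hypothesis each. The CO₂-reducing scenario assumes an
H₂-rich hydrothermal-type setting (pH₂ = 0.01 atm, pCO₂ = 0.2 atm) in
which the strongly exergonic methyl transfer to coenzyme M pulls most of
the 2.5 mM coenzyme-M pool into methyl-S-CoM (solved value ≈ 2.3 mM).
The methanol scenario holds methanol at 75 nM — the scarce-substrate
regime of marine-sediment methylotrophs — which leaves the same pool
almost entirely as free HS-CoM (solved methyl-S-CoM ≈ 0.012 mM). The
terminal reductase step is modelled as the dissipative sink (fixed
ΔG = −30 kJ/mol) in both scenarios, so the methyl-S-CoM prediction is an
upstream-equilibrium property, insensitive to the exact sink value.
Pool totals (methanofuran 1.5, methanopterin 2.0, coenzyme M 2.5,
coenzyme B 1.0, F420 0.5 mM) sit in the ranges measured for methanogens.
Users studying other conditions should edit the YAML, not the code.

## Biosynthetic capacity

`allowed_missing()` is the size-dependent tolerance rule — 0 missing
genes for pathways of ≤ 3 genes, 1 for 4–5, 2 for 6–10, 3 for 11–15, 4
for ≥ 16 — and `score_genomes()` marks a genome capable of a pathway
when its unsatisfied gene count stays within that tolerance. Presence is
binary (one annotation hit suffices); copy number is deliberately
ignored. Isoenzyme alternatives are expressed in the catalogue as
any-of groups that count as a single gene for the size rule. The
shipped 36-pathway scaffold (22 amino acids, 14 vitamins/cofactors)
carries *synthetic placeholder* family ids — the real pathway-to-family
mapping is manual curation the user supplies as data — so capacity
counts live on the 0–36 scale while the toy catalogue exercises every
rule branch.

## Ancestral growth temperature from 16S uracil content

`uracil_fraction()` computes `#U / (#A+#C+#G+#U)` over unambiguous,
ungapped sites (T read as U; ambiguity codes other than N are rejected
loudly rather than part-counted). `fitch_ancestral()` reconstructs
ancestral sequences by per-site Fitch parsimony with deterministic
alphabetical tie-breaking; gaps and N at leaves act as fully missing
states. Fitch parsimony is a deliberate, documented stand-in for
maximum-likelihood marginal reconstruction: the downstream statistic is
coarse base composition, for which a deterministic, dependency-free
parsimony reconstruction suffices, and an ML reconstruction under a
reversible model would be an extension, not a requirement. Two known
consequences: ancestral compositions are mildly shrunk toward the
tie-break state, and recovery quality varies with tree shape — the
end-to-end synthetic experiment (20 leaves, 500 sites, Brownian
temperature trait with σ = 25 °C per unit branch length, uracil fraction
linear in the trait) achieves Spearman ≥ 0.8 between reconstructed and
true ancestral temperatures at the suite's fixed seed, with replicate
means around 0.7–0.8.

The uracil-to-temperature map itself (`ogt_model()`) is configuration:
the published correlation's coefficients are supplied by the user, never
hardcoded as truth, and predictions outside the model's calibrated
fraction domain are flagged, not clipped. `fit_ogt_model()` provides the
ordinary-least-squares route used in parameter-recovery tests. Whether
composition should be computed on all sites or a stem-region mask is
exposed as the `sites` argument of `ancestral_ogt()` (default: all
sites).

## Synthetic data

All generators are pure functions of their seed (the caller's RNG state
is saved and restored), and one global seed fans out to per-component
child seeds by fixed offsets, so adding a generator never perturbs
existing streams.

* `sim_species_tree()`: forward birth–death simulation conditioned on
  the requested extant leaf count, cut at a uniform time before the next
  event and pruned of extinct lineages — rooted, binary, ultrametric.
* `sim_gene_tree_dtl()`: grows a gene family top-down with per-branch
  duplication/transfer/loss probabilities; each copy experiences at most
  one event per species branch, at a uniform position. Transfer
  recipients are drawn uniformly among branches overlapping the event
  time on the ultrametric species tree, which makes every simulated
  transfer satisfy the reconciliation model's incomparability constraint
  by construction; when no contemporaneous recipient exists the draw
  degrades to no event. The complete truth log is returned, and
  `replay_event_log()` rebuilds the identical tree from it — an identity
  the suite checks on 1,000 random configurations.
* `sim_sequences_with_trait()`: Brownian trait, linear trait-to-uracil
  map clipped to [0.05, 0.95] (clipping is counted and reported),
  site-independent sequence draws.
* `sim_genome_content()`: independent per-family dropout with
  self-consistent truth flags.

What the generators deliberately do *not* emulate: substitution-model
realism (no GTR/Γ; sequence sites are i.i.d. given the composition
target), rate heterogeneity across lineages, replacement transfers
(transfers add a copy; they never displace the vertical copy), gene
conversion, and annotation noise in gene content. Passing tests
therefore demonstrate correctness of the algorithms under their stated
models, not robustness to every artifact of real data.

## The family protocol

`run_family_protocol()` chains the stages the way a gene family is
analysed end to end: candidate rootings (outgroup first when available,
then midpoint, MAD, reconciliation-based), the consensus rule, the
transfer-cost sweep on the consensus branch, then support aggregation at
the calibrated `T` with `D ∈ {T/4, T/2, 3T/4}`. Every run emits a
manifest (resolved config, seed, input digests, package version,
timestamps); identical seeds and inputs reproduce identical primary
outputs, which the suite asserts. `run_thermo_scenarios()` solves
scenario configs side by side and places methyl-S-CoM first in the
comparison table, since that intermediate is the axis on which
CO₂-reducing and methyl-reducing methanogenesis differ. These functions,
together with the reading/writing helpers, are the package's interface;
they are ordinary R functions intended for scripts and sessions.

## Problem sizes and known limitations

The suite's problem sizes — 200 brute-force comparisons at ≤ 6 leaves,
100 planted-transfer replicates on 8-leaf trees, 30 MAD grid
comparisons, the exhaustive 2¹⁵ consensus truth table, 1,000 replay
identities, 20-leaf/500-site temperature recovery — were chosen so the
whole battery runs in a few minutes on one core while still exercising
every co-optimum and boundary case the algorithms have.

Limitations worth knowing: the DP is `O(|gene| · |species|²)` in pure R
and is comfortable at the tens-of-leaves scale of curated protein
families, not at thousands of taxa; dated (time-consistent)
reconciliation, likelihood-based reconciliation, and root inference via
nonreversible substitution models are out of scope; the thermodynamic
solver handles chain-structured pathways with explicit adjustable
species and does not attempt kinetics, ionic-strength corrections, or
ΔG°′ estimation from formation energies; and the capacity scaffold's
family ids are placeholders until a user supplies real curation.
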