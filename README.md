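# methanotrace

Tools for studying how methanogenesis and the domain *Archaea*
co-evolved. The package is aimed at molecular evolutionists and
geomicrobiologists who work with gene trees of methanogenesis enzymes
(F430 biosynthesis CfbABCDE, the Mtr methyl-transfer complex, the
methyl/alkyl-S-CoM reductase family), archaeal species trees, genome
annotations, and 16S rRNA alignments — and who want the bespoke
computations behind such studies as tested, reusable functions.

## What it computes

**Gene-tree/species-tree reconciliation.** Undated
duplication–transfer–loss (DTL) parsimony: given a rooted gene tree
*G*, a rooted species tree *S*, and a leaf map, find an event history of
minimum cost *D*·#dup + *T*·#transfer + *L*·#loss (speciation free),
with transfers allowed between incomparable species branches. The
dynamic program is exact (integer cost arithmetic) and is validated
against exhaustive enumeration. On top of it: root search over all
2n − 3 rootings (`opt_root_dtl`), calibration of the smallest transfer
cost recovering a target rooting (`optimize_transfer_cost`), and event
supports aggregated over repeated runs with duplication costs
{*T*/4, *T*/2, 3*T*/4} (`aggregate_reconciliations`).

**Multi-method rooting with a consensus rule.** Outgroup, midpoint,
minimal ancestor deviation (MAD; per-branch closed-form minimization of
the RMS relative deviation |2·d(a,i)/d(i,j) − 1|), and
reconciliation-based rooting, combined by the rule: accept a root branch
only if at least two methods and a majority of protein subunits support
it, with outgroup evidence reported first when available.

**Quasi-equilibrium pathway thermodynamics.** Given per-reaction ΔG°′,
fixed boundary species, and conserved cofactor pools (methanofuran,
methanopterin, coenzymes M and B, the F420/F420H₂ redox couple pinned to
the H₂ partial pressure), solve each step for ΔG = ΔG°′ + RT·ln Q equal
to its target (0, or a fixed dissipation/investment value) and iterate
to a conserving fixed point. The shipped CO₂-reducing and
methanol-reducing scenarios predict intracellular methyl-S-CoM — the
substrate of the terminal reductase — under H₂-rich versus
methanol-scarce conditions.

**Biosynthetic capacity.** Pathway-completeness scoring of genomes with
a size-dependent tolerance for missing genes (0 missing for ≤ 3-gene
pathways, 1 for 4–5, 2 for 6–10, 3 for 11–15, 4 for ≥ 16), over a
configurable catalogue of 22 amino-acid and 14 vitamin/cofactor
pathways.

**Ancestral growth temperature.** Fitch-parsimony ancestral 16S
sequences, uracil fractions over unambiguous sites, and a configurable
linear uracil→OGT correlation.

**Synthetic data.** Seeded generators for ultrametric birth–death
species trees, gene trees with logged D/T/L events (replayable
exactly), trait-linked RNA alignments, and genome content under
dropout — every stage is testable with known ground truth.

## Worked example

```r
library(methanotrace)

# --- thermodynamics: CO2-reducing vs methanol-reducing methanogenesis
co2  <- read_thermo_model(system.file("extdata/thermo/co2_reduction.yaml",
                                      package = "methanotrace"))
meoh <- read_thermo_model(system.file("extdata/thermo/methanol_reduction.yaml",
                                      package = "methanotrace"))
cmp <- run_thermo_scenarios(list(co2, meoh))
head(cmp$comparison, 4)
#>     species co2_reduction methanol_reduction
#> 1 CH3-S-CoM          2.27             0.0123
#> 2        H2          0.01                 NA
#> 3       CO2          0.20                 NA
#> 4       CH4          0.50             0.5000
```

Under H₂-rich boundary conditions the chain of per-step equilibria pulls
most of the 2.5 mM coenzyme-M pool into methyl-S-CoM (2.27 mM); with
methanol held at sediment-porewater levels the same pool stays almost
entirely free (0.012 mM) — a ~185-fold contrast in the terminal
reductase's substrate concentration between the two lifestyles.

```r
# --- a simulated gene family through the full rooting/reconciliation protocol
st  <- sim_species_tree(8, seed = 11)
fam <- sim_gene_tree_dtl(st, dup = 0.03, transfer = 0.05, loss = 0.03, seed = 2)
out <- run_family_protocol(fam$gene, st, fam$map, t_grid = c(2, 4, 8),
                           n_runs = 100, seed = 1)
out$consensus$accepted         #> TRUE   (mad + midpoint + reconciliation agree)
out$transfer_cost              #> 2      (smallest T recovering the consensus root)
out$reconciliation
#> <DTL reconciliation> cost=6 | S=9 D=0 T=3 L=0
head(as.data.frame(out$supports), 5)
#>   gene_node event support
#> 1        14     S       1
#> 2        15     S       1
#> 3        16 T->s2       1
#> 4        17     S       1
#> 5        18     S       1
```

The support table reads: gene node 16 is explained as a horizontal
transfer whose recipient is species branch `s2` in 100% of the
aggregation runs; every other internal node is a plain speciation.

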