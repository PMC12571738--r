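# fermecol

Community ecology of fermented-grain (Baijiu *jiupei*) microbiomes, from
feature count tables to assembly-process inference.

Solid-state grain fermentation is driven by a succession of bacteria and
fungi in which a handful of taxa (*Lactobacillus*, *Saccharomyces*)
sweep to dominance while hundreds of rare taxa persist at trace
abundance. Understanding that succession requires more than composition
plots: which taxa are *always* vs *conditionally* rare, whether the
abundant and rare sub-communities restructure together, which taxa hold
co-occurrence networks together, and whether turnover is driven by
deterministic selection or by stochastic dispersal and drift. `fermecol`
implements that downstream analysis as a tested, seeded R pipeline
operating on OTU/ASV count tables — no sequencing data required for
development or testing, thanks to built-in synthetic generators.

## What it computes

**Rarity classification.** Each feature's per-sample relative abundance
profile is assigned to one of six categories by two thresholds (0.01%
and 1%, strict inequalities): always abundant (AAT), conditionally
abundant (CAT), conditionally rare and abundant (CRAT), always rare
(ART), conditionally rare (CRT), and moderate (MT). AAT/CAT/CRAT form
the abundant group, ART/CRT the rare group.

**Diversity and ordination.** Shannon entropy (nats), exact
hypergeometric rarefaction E[S<sub>n</sub>], Bray–Curtis
dissimilarity BC(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ), principal coordinates
(Gower-centered eigendecomposition, negative eigenvalues reported, no
correction), and PERMANOVA with p = (1 + #{F\* ≥ F}) / (1 + n_perm).

**Co-occurrence networks.** Per-stage Spearman correlation networks
over the abundant+rare features, keeping edges with |ρ| > 0.8 and
p < 0.05 (t approximation); greedy-modularity modules; per-node
within-module connectivity Zᵢ = (κᵢ − κ̄)/σ_κ and participation
Pᵢ = 1 − Σₘ(κᵢₘ/kᵢ)²; keystone taxa are module hubs (Zᵢ > 2.5),
connectors (Pᵢ > 0.62) or network hubs (both).

**Assembly inference.** Abundance-weighted βMNTD between samples, its
standardized effect size βNTI against a 999-replicate tip-shuffle null,
and the abundance-based Raup–Crick index RC_bray against an
occupancy/abundance assembly null. Each sample pair is then classified:
heterogeneous selection (βNTI > 2), homogeneous selection (βNTI < −2),
dispersal limitation (|βNTI| < 2, RC > 0.95), homogenizing dispersal
(|βNTI| < 2, RC < −0.95), or undominated.

**Synthetic data.** Seeded generators for two-stage succession tables
(days 0–5, 7, 9, 11, 14 × 2 batches, log-normal abundances, a
takeover feature ramping to dominance), planted correlation blocks,
Yule phylogenies, and communities assembled under known ecological
processes — every downstream classifier can be scored against planted
ground truth.

## Worked example

```r
library(fermecol)

sim <- simulate_succession(succession_scenario(n_features = 190, seed = 1))
tab <- filter_min_frequency(sim$table)
#> filter_min_frequency: removed 31 of 190 features below 5e-05

a <- classify_rarity(tab)
rarity_counts(a)
#>   category     n
#> 1 AAT          3
#> 2 CAT         23
#> 3 CRAT         1
#> 4 ART          0
#> 5 CRT        109
#> 6 MT          23

d <- bray_curtis(tab)
pcoa_ordination(d)
#> <pcoa_ord> 20 samples, 15 positive axes (4 negative eigenvalues reported)
#> axis 1-2 explain 69.6% + 22.1%

permanova(d, tab$metadata$stage, n_perm = 999, seed = 2)
#> PERMANOVA: pseudo-F(1, 18) = 11.419, R2 = 0.388, p = 0.001 (999 perms)

rare <- subset_group(tab, a, "rare")
beta_nti(rare, simulate_tree(190, seed = 3), reps = 199, seed = 4)
#> <beta_nti> 20 samples, 190 pairs (sampled null, 199 reps, abundance-weighted)
#> betaNTI range -1.89 .. 2.38; 98.4% within (-2, 2)
```

Read that as: after the low-frequency filter, 109 of 159 features are
conditionally rare; the community differs sharply between the two
fermentation stages (PERMANOVA p at the permutation floor, R² ≈ 0.39,
and the first two ordination axes carry ~92% of the positive inertia);
and the rare sub-community's phylogenetic turnover is almost entirely
inside the |βNTI| < 2 stochastic band — its assembly is not dominated
by selection.

One-call orchestration of the whole analysis (filter → rarity →
diversity → per-stage networks → per-group assembly, all artifacts as
TSV/JSON/GraphML plus a checksummed manifest):

```r
cfg <- pipeline_config(table = sim$table, tree = simulate_tree(190, seed = 3),
                       kingdom = "bacteria")
run_pipeline(cfg, "out/", seed = 1)
```

`tidy()`, `glance()` and `autoplot()`/`plot_*()` methods are provided
for ordinations, PERMANOVA fits, networks and βNTI results.

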