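---
title: "Methods: rarity, networks and assembly inference in fermented-grain microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rarity, networks and assembly inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fermecol` analyzes the microbial ecology of solid-state grain
fermentation from feature (OTU/ASV) count tables: who is rare and who
is abundant, how the community restructures across fermentation stages,
which taxa hold the co-occurrence network together, and whether
community assembly is governed by selection or by stochastic processes.
This vignette explains each method, its assumptions, the tunable
parameters, and the design decisions taken where more than one
defensible choice existed.

## Data model

The central container is a `feature_table`: an integer count matrix
(features × samples) plus a per-sample metadata tibble (`sample_id`,
`day`, `batch`, `stage`). Counts are validated on construction
(non-negative integers, unique ids, metadata coverage). Fermentation
*stages* are configuration, not inference: day ranges are mapped to
stage labels by `assign_stages()`, with defaults reflecting the
observed dynamics of the two kingdoms — bacteria restructure late
(S1 days 0–5, S2 days 7–14), fungi early (S1 days 0–1, S2 days 2–14).

Before any analysis, `filter_min_frequency()` removes features whose
total count over all samples falls strictly below a fraction of the
grand total (default 5e-5, i.e. 0.005%, the conventional
post-denoising filter). The filter is global rather than per-sample,
matching how denoising pipelines apply a single table-wide threshold,
and a feature sitting exactly at the threshold is retained.

## Rarity classification

Each feature's per-sample relative abundance profile is classified by
two thresholds, `low` = 1e-4 (0.01%) and `high` = 1e-2 (1%), into six
categories: AAT (above `high` everywhere), CAT (above `high`
somewhere, never below `low`, not always above `high`), CRAT (spans
both extremes), ART (below `low` everywhere), CRT (below `low`
somewhere, never above `high`, not always below `low`), MT (strictly
between the thresholds everywhere). AAT/CAT/CRAT form the *abundant*
group, ART/CRT the *rare* group, MT the *moderate* group.

Two decisions deserve note:

* **Boundary handling.** All comparisons are strict; a value exactly
  equal to a threshold counts as neither "high" nor "low", so it falls
  in the moderate band. This is the only convention under which the six
  categories form an exhaustive, mutually exclusive partition — the
  package's partition-completeness test exercises 10,000 random
  profiles drawn log-uniformly over [1e-7, 0.5].
* **Genus-level summaries.** When rare/abundant labels are wanted at
  genus level, counts are aggregated to genus first
  (`aggregate_by_rank()`, which conserves per-sample totals and keeps
  unrelated unclassified lineages apart by suffixing the deepest
  classified parent rank) and the aggregated table is classified with
  the same thresholds. Classifying genera directly, rather than
  inheriting labels from member features, avoids ambiguity when a
  genus's members straddle categories.

Classification depends only on relative abundances, so it is invariant
to per-sample sequencing depth — a property tested by rescaling one
sample's counts.

## Diversity, ordination, group tests

Shannon diversity uses the natural log (nats), the default in ecology
toolkits. Rarefaction uses the exact hypergeometric expectation
E[S_n] = Σᵢ [1 − C(N−Nᵢ, n)/C(N, n)], computed in log space via
`vegan::rarefy()`. Bray–Curtis dissimilarity is computed on per-sample
relative abundances when given a `feature_table`, so depth differences
are not mistaken for turnover; a plain matrix is used as given.

PCoA (`pcoa_ordination()`) eigendecomposes the Gower-centered matrix
−½ J D² J via `ape::pcoa()`. Negative eigenvalues — expected for
semi-metric dissimilarities like Bray–Curtis — are reported, not
corrected (no Cailliez/Lingoes), matching the default behavior of the
common implementations and keeping axis proportions interpretable.
Axis signs are made deterministic by flipping each axis so its
largest-magnitude loading is positive. Proportions explained are
computed over the positive eigenvalues only.

PERMANOVA (`permanova()`) implements the ADONIS sums-of-squares
decomposition directly from the distance matrix (SS = Σ d²/n within
strata), with pseudo-F assessed against free permutations of sample
labels and p = (1 + #{F\* ≥ F}) / (1 + n_perm). No permutation strata
are used — the sampling design has no blocking structure. The
implementation is cross-checked in the tests against both an
exhaustive enumeration of labelings on a 4-sample fixture and
`vegan::adonis2()`, and its type-I error is verified by simulation
(500 exchangeable null datasets, n = 12, 199 permutations; the
rejection rate at α = 0.05 must fall in [0.03, 0.08]). One subtlety
the tests document: with small balanced designs, random permutations
occasionally recreate the observed partition exactly, tying F, so the
1/(n_perm+1) floor is only attainable when the partition space is
large relative to n_perm.

## Co-occurrence networks and keystones

Networks are built per kingdom × stage on the union of abundant and
rare features. Spearman correlations use midranks for ties; p-values
use the t approximation t = ρ√((n−2)/(1−ρ²)) on n−2 degrees of
freedom. Features occurring in fewer than `min_prevalence` (default 3)
samples of the stage subset, or constant across it, are excluded —
rank correlation is uninformative without variation. An edge requires
|ρ| strictly above 0.8 **and** p strictly below 0.05; raw p-values are
the default (the stringent |ρ| threshold is the primary filter), with
optional Benjamini–Hochberg correction behind `p_adjust = "BH"`.
Isolated features are dropped from the node set.

Modules are found by greedy modularity maximization
(Clauset–Newman–Moore, via igraph) on the unweighted, unsigned graph;
with a fixed vertex order the algorithm is deterministic, and repeated
runs agree exactly. Zi (within-module degree z-score, population sd,
0 for degenerate modules) and Pi (participation coefficient, 0 for
isolated nodes) follow the original topological-role formulation on
the unsigned graph. Roles use the conventional thresholds: module hub
Zi > 2.5, connector Pi > 0.62, network hub both, peripheral otherwise;
keystone = non-peripheral. Topology summaries report node/edge counts,
percent positive edges, percent rare nodes (overall and among
keystones), average degree, average local clustering (0 for degree
< 2), Freeman degree centralization Σ(k_max − kᵢ)/((n−1)(n−2))
(undefined below 3 nodes), and modularity Q. All node-level metrics
are verified against independent brute-force recomputations on small
fixtures, to 1e-12.

## Assembly inference

**βMNTD.** For samples a, b, the abundance-weighted mean distance from
each taxon to its phylogenetically nearest taxon in the other sample,
averaged over both directions. A taxon present in both samples is its
own nearest taxon (distance 0). Abundance weighting is the default
(`weighted = FALSE` gives uniform weights over present taxa; note the
unweighted form averages the two directional means, which differs from
implementations that pool both directions when richness is unequal).
Internally an all-pairs matrix identity is used (βMNTD =
½(G + Gᵀ), G = FᵀM with M the per-sample nearest-taxon distance
profile), which makes the 999-replicate null loop tractable; the fast
path is tested against the naive per-pair loop and against
`picante::comdistnt()`.

**βNTI.** The standardized effect size of βMNTD against a tip-shuffle
null: each replicate permutes the tip labels of the patristic distance
matrix uniformly at random, breaking the phylogeny–abundance
association while preserving both marginals; one shuffle serves all
sample pairs in a replicate. |βNTI| > 2 is read as deterministic
selection. In `mode = "exhaustive"` (≤ 8 tips) all n! permutations are
enumerated and the null standard deviation uses the population
(divide-by-n) form, because the enumeration *is* the complete null
distribution; sampled mode uses the sample sd as an estimator.
Degenerate pairs (null sd = 0, e.g. both samples containing exactly
the same taxa, or a star tree with equal branch lengths) yield `NA`
with a warning rather than ±∞, and are excluded from downstream
fractions with a logged count.

**RC_bray.** The abundance-based Raup–Crick index: for each pair,
999 null communities preserve each sample's richness and total count,
draw species identities without replacement with probability
proportional to occupancy, seed each with one individual, and fill the
remainder multinomially in proportion to the species' summed relative
abundance across samples. Observed and null Bray–Curtis are both
computed on relative abundances. RC = 2·[(#null < obs) +
0.5·(#null = obs)]/reps − 1 ∈ [−1, 1]; ties use exact float equality
and are counted, not perturbed.

**Process partition.** Pairs are labeled in rule order: heterogeneous
selection (βNTI > 2), homogeneous selection (βNTI < −2), dispersal
limitation (RC > 0.95), homogenizing dispersal (RC < −0.95), else
undominated. All rules are strict, so boundary values (|βNTI| = 2,
|RC| = 0.95) fall through to the weaker, non-selection side. Process
fractions are reported per pairing stratum — within-stage (S1, S2),
cross-stage, and pooled over all pairs — because it is genuinely
ambiguous which grouping a reader will want; both are emitted. The
rare and abundant sub-communities are analyzed on tables subset to
their member features (with the tree pruned to match), giving each
group its own βNTI distribution and process profile.

## The synthetic-data generators

The generators exist so that every classifier in the pipeline can be
scored against planted ground truth.

* `simulate_succession()` emulates the study design the package
  targets: 10 sampling days (0–5, 7, 9, 11, 14) × 2 batches,
  multinomial sampling at 20,000 reads, log-normal base abundances
  (sdlog 2.5, so rare features dominate the feature count while a few
  dominate reads), a stage-2 baseline perturbation, and a takeover set
  whose share ramps log-linearly to 90% across stage 2 — the
  *Lactobacillus*-style sweep. Ground-truth rarity categories are
  computed from the *expected* (pre-sampling) relative abundances, so
  sampling noise near a threshold is measurable classifier error, not
  label noise.
* `simulate_correlated_block()` plants blocks of features sharing a
  latent per-sample log-abundance factor (anti-phase members ride the
  negated factor). Block members get an elevated baseline so anti-phase
  members cannot bottom out at zero counts, which would destroy their
  rank signal. Background features fluctuate independently and
  calibrate the false-edge rate.
* `simulate_assembly()` plants ecological processes. The phylogeny is
  partitioned into habitat clades (average-linkage clustering of
  patristic distances, `n_env` = 3 by default); heterogeneous selection
  assigns samples round-robin to different clades, homogeneous
  selection confines every sample to the same clade, neutral drift
  draws every sample from the unfiltered pool. Habitat filtering is
  strict (zero suitability outside the clade) by design: during
  development, trait-kernel filtering — a Gaussian niche on a
  Brownian-motion trait — proved too weakly aligned with phylogeny at
  30 taxa to plant a reliable signal, and even a single stray read
  inside the partner sample's clade provides a zero-distance nearest
  neighbour that erases the turnover the scenario is meant to create.
  Discrete habitat-clades are the cleanest generative picture of
  "different environments select different lineages".

What the generators do **not** emulate: PCR/chimera artifacts,
compositional count correlation induced by closure, taxonomy beyond
mock genus labels, overdispersed (non-multinomial) sampling, and any
coupling between the rarity structure and the phylogeny. Passing the
planted-recovery tests therefore demonstrates algorithmic correctness
under the stated generative models, not robustness to every artifact
of real amplicon data.

## Numerical choices and degenerate inputs

* Rarity boundaries: strict inequalities; threshold values fall in the
  moderate band.
* Network boundaries: |ρ| = 0.8 exactly is not an edge; p = 0.05
  exactly is not significant.
* βNTI: null sd of 0 gives `NA`, never ±∞; exhaustive mode uses the
  population sd.
* RC ties: exact float equality, half weight.
* PCoA signs: largest-magnitude loading positive, so outputs are
  byte-reproducible.
* PERMANOVA p: the add-one estimator, never exactly 0.
* All stochastic functions take an explicit `seed`; `run_pipeline()`
  derives per-stage seeds arithmetically from one run seed, and
  identical config + seed yields byte-identical artifacts (verified by
  checksum in the tests).

## Problem sizes used by the test suite

Unit fixtures are 2–12 nodes/tips where exact enumeration or hand
computation is the oracle. Statistical properties use: 10,000 random
profiles (rarity partition); a 1,000-feature planted rarity table; 500
simulated datasets × 199 permutations (PERMANOVA calibration); 999
null replicates for βNTI/RC properties at 30 taxa × 8 samples; and a
bundled two-kingdom scenario (190- and 500-feature tables, 20 samples
each) run twice through the full pipeline at 99 replicates to verify
byte-identical artifacts. These sizes were chosen so the full suite
exercises every statistical claim in well under an hour on a single
core while keeping Monte-Carlo error far from each test's margin.

## Known limitations

* The homogeneous-selection generator does not reliably push βNTI
  below −2 at 30 taxa: within-clade turnover among close relatives is
  a weak clustering signal at this community size, and many same-clade
  sample pairs are compositionally identical (degenerate null). The
  scenario is retained for completeness; the recovery tests assert
  only the heterogeneous and neutral signatures.
* Spearman co-occurrence on relative counts inherits compositional
  bias; the package deliberately reimplements the conventional
  pipeline rather than a compositionally-aware estimator (SparCC,
  SPIEC-EASI), which is out of scope.
* βNTI on sub-communities whose features are present in every sample
  is undefined (no turnover); abundant sub-communities of low-richness
  synthetic tables often hit this, and the pipeline reports the
  affected pair counts rather than inventing values.
* Process fractions over few samples rest on few pairs; the `n`
  columns in all outputs are there to keep that visible.
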