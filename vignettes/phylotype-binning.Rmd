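---
title: "Phylotype binning from phylogenetic placements: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylotype binning from phylogenetic placements: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylobin)
```

## The problem

16S rRNA amplicon studies target different variable regions of the gene
with different primers, so the amplicon sequence variants (ASVs) they
produce are not directly comparable across studies: the same organism
yields literally disjoint sequences under V1--V2 versus V4 primers.
Closed-reference OTUs and taxonomic labels harmonize studies only up to
the resolution and biases of a reference database. Phylogenetic
placement offers a taxonomy-free alternative: every ASV, whatever its
region, is located on a common full-length 16S reference phylogeny, and
amplicons of the same underlying allele land in the same small subclade.
`phylobin` turns those placements into a count-ready feature:
**phylotypes**, bins of ASVs whose placements lie within a chosen
phylogenetic distance of each other.

## The distance

An ASV's placement (a jplace record) is a set of candidate attachment
points -- edge number, distal offset, pendant length -- weighted by
like-weight ratio (lwr). We treat it as a probability mass distribution
on the tree: one point per row at (edge, distal offset), with weights
lwr renormalized to sum one. Renormalization is a deliberate choice:
placement engines omit edges "without meaningful likelihood", so raw lwr
sums vary by engine and truncation policy, and renormalizing makes
records comparable. Whether the original implementation renormalized is
not documented anywhere we could check; this is our documented
convention.

The distance between two ASVs is the Kantorovich--Rubinstein (KR,
1-Wasserstein, earth-mover) distance between their mass distributions
under the tree's path metric -- the placement-to-placement analogue of
weighted UniFrac. For exponent 1 it is computed exactly by one
post-order sweep: every edge segment (segments delimited by attachment
points) contributes |net mass below the segment| x segment length.
This equals minimum-cost transport; the test suite verifies that claim
against an independent successive-shortest-path transport solver and
verifies point-mass distances against shortest paths on a subdivided
graph.

Pendant lengths are **excluded** from inter-ASV distances by default.
Pendant length measures amplicon-versus-reference divergence, which
differs systematically by primer; including it would push amplicons of
the same allele apart -- precisely the artifact phylotypes exist to
remove. `include_pendant = TRUE` is available for sensitivity analysis
(each unit of mass pays its row's pendant once, which is exact for the
exponent-1 transport). A `best_only` mode reduces each record to its
top-lwr placement; the full distribution is the default because the
original tool's choice is not recorded and the full KR uses all of the
engine's evidence.

## The binning algorithm

Exhaustive pairwise distances over the hundreds of thousands of ASVs a
meta-analysis produces are O(n^2) and impractical, so binning divides
first and conquers second:

1. **Pre-group** ASVs that share at least one mass-bearing placement
   edge (connected components under that relation, via union-find).
2. **Merge** pre-groups whose placement LCAs are closer than the
   clustering threshold, transitively; merged groups recompute their
   LCA.
3. **Cluster** each merged group exhaustively: full within-group KR
   matrix, agglomerative clustering, flat cut at the threshold.
4. **Name** the resulting phylotypes.

Step 2's merge comparison is strict (`separation < threshold`), as is
the cluster cut: two ASVs exactly at the threshold distance stay apart.
The cut is implemented by counting merges below the threshold rather
than cutting at a height, so strictness is exact rather than
epsilon-fudged.

The divide is sound for disjoint clades: if two merged groups' LCAs are
at least the threshold apart and their mass lies inside their clades,
every cross-group pair is at least that separation apart, so skipping
those pairs cannot change the single-linkage result. Two caveats are
worth knowing. When one group's clade nests inside another's, the
LCA-separation bound no longer lower-bounds cross-pair distances;
`merge_pregroups()` emits a message when it detects nesting so
divergence can be audited against `brute_force_bin()`. And when
placement mass sits on the LCA's own edge (mass "above" the clade), the
bound erodes by up to that overhang; with dispersions far below the
threshold this margin is negligible, and the acceptance suite confirms
exact agreement with the exhaustive computation under the validation
conditions.

**Linkage.** The operational definition -- sequence variants at less
than the threshold distance apart cluster together -- is single-linkage
semantics, so `single` is the default; `average` and `complete` are
provided as options. Single linkage also gives the threshold
monotonicity property (phylotype count non-increasing in threshold)
that the granularity comparisons rely on.

**Naming.** Phylotypes are named `pt<TT>__<IIIII>`: `TT` encodes the
threshold (`round(threshold * 10)`, so 0.1 -> `pt01`, 0.5 -> `pt05`,
1.0 -> `pt10`) and the five-digit index orders phylotypes by descending
total read count when a count table is supplied, else by descending
member count, ties broken by the lexicographically smallest member ASV
id. The index ordering is our convention; only the grammar is fixed by
precedent.

## Post-hoc integration

New studies are integrated without re-binning: place the new ASVs on the
**same** tree, then (1) take each existing phylotype's placement LCA,
(2) compute each new ASV's KR distance to every LCA (for a point target
this reduces exactly to the weighted mean path distance, making
assignment linear in placement rows), (3) assign to the nearest
phylotype if that distance is strictly below the threshold, ties to the
lowest phylotype index. Unassignable ASVs are reported and can be
spawned into new phylotypes whose names continue the index sequence;
existing memberships are never altered. Models store an MD5 digest of
the serialized tree and refuse placements made on any other tree --
phylotypes are only comparable when generated against the same
phylogeny, and a silent mismatch would corrupt a harmonization without
any visible symptom. Distance to the LCA (not to the nearest member) is
the default because it is the documented procedure; a `nearest_member`
mode exists for sensitivity analysis.

## Counts, normalization, recruitment

`phylotype_counts()` collapses specimen-by-ASV counts to
specimen-by-phylotype counts; ASVs missing from the assignment fall
into an explicit `unclassified` column so per-specimen totals are
conserved exactly and the unassigned fraction stays auditable.
`normalize_counts()` scales each specimen to 10,000 pseudo-counts by
default; values stay real-valued because no rounding rule is part of
the definition and reals keep Bray--Curtis exact. `bray_curtis()`
delegates to `vegan::vegdist`; a pair of all-zero specimens is
undefined (`NaN`), never silently zero.

`recruit()` implements bounded-best-hit reference selection for
building ASV-tailored trees: floor hits at 80% identity, keep each
ASV's best hits (ties kept), retain references that are best hits for
at least two ASVs, then backfill one reference per uncovered ASV
preferring zero ambiguous bases, then precise taxonomy, then length,
then lexicographic ref id. The backfill priority is our reading of
"longest alleles with no ambiguous bases and precise taxonomy"; the
count restored per ASV (one) is configurable since no count is
documented. The search itself (vsearch, max_accepts 10) is out of
scope; the module consumes its tabular output, which keeps the logic
testable without external binaries. The ~10-alleles-per-ASV objective
is reported as a diagnostic, not fed back into the filter.

## The synthetic validation design

The generator emulates the in-silico validation: communities with a
known allele of origin for every amplicon, five primer sets, and
platform-typical depths (50,000 reads per specimen MiSeq-like, 5,000
for 454-like runs).

* `simulate_tree(n_leaves, seed, branch_scale)`: Yule-style sequential
  attachment with exponential branch lengths. Defaults used in the
  validation runs: 100--200 leaves, `branch_scale = 0.15`
  substitutions/site, giving tip-to-root depths of roughly 1--2,
  comparable to a de-novo full-length 16S tree.
* `simulate_placements()`: `n_alleles` source leaves chosen greedily
  pairwise at least `min_separation` apart (default 0.5, about five
  times the 0.1 binning threshold); per allele x primer one ASV whose
  mass points sit within `dispersion` of the source leaf, weights from
  a symmetric Dirichlet. Dispersion defaults in the 0.005--0.02 range,
  calibrated to the illustrated same-allele multi-primer subclades
  (about 0.1 deep) rather than to measured data, which nothing in the
  public record provides.
* `simulate_counts()`: log-normal allele abundances (sigma = 2, a
  gut-like rank-abundance spread), multinomial reads at exact depth,
  one primer per specimen.

Dispersion is modeled geometrically -- mass near the source leaf --
rather than by simulating sequences through an alignment and placement
engine. This isolates the binning algorithm with controllable ground
truth; it deliberately does **not** model placement multimodality
across distant clades, reference-tree misspecification, chimeras, or
primer-specific placement bias. Passing the recovery tests therefore
shows the algorithm is correct under its stated geometry, not that any
particular real dataset will bin at one allele per phylotype.

Accuracy is scored by `alleles_per_phylotype()` (lumping; ideal 1) and
`phylotypes_per_allele()` (splitting; ideal 1), and granularity by
`rarefaction_curve()` (reads subsampled without replacement from the
pooled table, 100 replicates per depth).

## Numerical choices and degenerate inputs

* Distal offsets overshooting the branch by <= 1e-6 are clamped
  (placement engines emit tiny overshoots); larger overshoots error.
* lwr rows must lie in [0, 1] and sum to (0, 1 + 1e-6]; an lwr floor
  for pruning rows exists but defaults to 0 (keep all), since no floor
  is documented.
* `{N}` edge annotations are accepted before or after the branch
  length, since jplace emitters differ on this.
* Basal trifurcations are accepted; the file's outermost node is the
  root, and all distances are root-independent (verified to 1e-9 under
  random rerooting).
* Serialized branch lengths carry 12 significant digits; round trips
  agree to 1e-12.
* A zero-read specimen yields `NA` assigned fraction and is dropped
  (with a warning) by normalization -- never reported as 0.
* `brute_force_bin()` refuses more than 5,000 records unless forced.

## Problem sizes in the shipped checks

The test and acceptance runs use 100--200-leaf trees, 40 alleles x 5
primers (200 ASVs), 20 random seeds for the recovery and equivalence
checks, 1,000+ oracle comparisons for the metric, and 10--12 specimens
at 5,000--50,000 reads -- sizes chosen so the whole validation design
runs comfortably on a laptop while still exercising every code path at
the documented study conditions.

## Known limitations

* Phylotypes are tied to their reference tree; there is no cross-tree
  translation (by design, enforced via the digest check).
* The divide-and-conquer guarantee is proven for disjoint clades;
  nested merged clades are flagged, not silently trusted.
* Exponent values other than 1 for the KR metric are exposed but not
  validated against an oracle.
* The generator's abundance model is a single log-normal; it does not
  emulate compositional structure such as enterotype-like clustering.

## A worked example

```{r example, eval = FALSE}
tree <- simulate_tree(150, seed = 42, branch_scale = 0.15)
sim <- simulate_placements(tree, n_alleles = 20, dispersion = 0.005,
                           min_separation = 0.5, seed = 42)
model <- bin_phylotypes(sim$pset, threshold = 0.1)
alleles_per_phylotype(model, sim$truth)$mean   # 1 when recovery is ideal
counts <- simulate_counts(sim$truth, n_specimens = 6, depth = 50000,
                          seed = 42)
ptc <- normalize_counts(phylotype_counts(counts, model))
D <- bray_curtis(ptc)
```
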