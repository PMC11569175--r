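# scmregions

Microenvironment analysis for 10x Visium spatial transcriptomics, starting
from per-spot **cell-state abundance** estimates (the output of mapping a
single-cell reference onto spots with a deconvolution model). The package
is aimed at analysts who have a multi-sample Visium cohort plus a
deconvolution result and want tissue regions, recurrent region markers,
and interface-level signaling statistics that are comparable across
samples — without clustering-based batch integration.

## What it computes

**SCM regions.** With `A` the spots-by-states abundance matrix pooled over
samples, NMF models `A ≈ W H` (nonnegative, Frobenius objective) are fit
for k = 5…12 components. For each component j the *top state* is
`argmax_s H[j, s]`; a k is admissible when all top states are distinct and
the **largest admissible k** is chosen — the finest partition in which
every component is still anchored by its own cell state. Spots take the
label `argmax_j W[i, j]`. These single-cell-mapping (SCM) regions are the
unit of all downstream analysis.

**Region-specific markers.** Per sample, one-vs-rest two-sided Wilcoxon
DE per region (regions ≥ 10 spots; mito/ribo genes excluded; BH within
sample × region; DE means log2FC ≥ 1 and p_adj < 0.05). Across samples, a
one-sided Fisher exact test on DE-instance counts (focal region vs all
others) with BH within region declares *region-specific markers*.

**Spatial statistics.** Hex-lattice graphs (6 neighbours, 3 rings ≈
300 µm), permutation neighbourhood-enrichment z-scores, proximal/distant
annotation around a focal region (anchored-pair rule), and interface
detection between region pairs (both interacting sets ≥ 10 spots).

**Signature scores.** Seurat-style bin-matched scoring (25
equal-frequency expression bins, 50 controls per bin), Welch t-tests with
quantile effect tiers (`*`/`**`/`***` when the comparison group's
70th/80th/90th percentile lies below the focal mean), and Spearman
correlation of per-sample focal-region fraction against non-focal
signature scores.

**Ligand–receptor interactions.** CellphoneDB-style permutation test of
side-mean co-expression between interface spot sets (1% detection gate,
1000 permutations, add-one p-value, BH per sample × interface), followed
by a one-sided Fisher test for interface-specific enrichment of active
pairs across samples.

A bundled generator (`simulate_cohort()`) produces Visium-like cohorts
with known ground truth — latent regions, planted markers, category
effects, a planted interface interaction — so the entire pipeline is
testable offline.

## Worked example

```r
library(scmregions)

cfg <- pipeline_config(
  sim = sim_config(n_samples = c(BPH = 1, TRNA = 2, NEADT = 2, CRPC = 1),
                   lattice_rows = 20, lattice_cols = 20, seed = 7),
  n_perms = 500, seed = 7)
res <- run_pipeline(cfg, out_dir = "run")

res$model
#> region_model: k = 8 chosen from 5..12 | top states: state4, state3,
#>   state7, state5, state2, state8, state1, state6

adjusted_rand_index(res$assignment$region, res$sim$truth$true_region)
#> [1] 1
```

The uniqueness rule stopped at k = 8 (each component anchored by a
different cell state) and the spot labels reproduce the simulated region
field exactly (adjusted Rand index 1). Per-sample region composition:

```r
round(res$regions$fractions[1:3, 1:5], 3)
#>         region1 region2 region3 region4 region5
#> BPH_01    0.242   0.078   0.142   0.162   0.090
#> TRNA_01   0.152   0.120   0.188   0.105   0.318
#> TRNA_02   0.312   0.265   0.050   0.085   0.062
```

The focal (club-like) component's marker table recovers the planted
markers — e.g. `gene21`…`gene26` were DE in 5–6 of 6 tested instances of
that region and nowhere else (Fisher p_adj ≈ 1e-5 to 4e-4). The
ligand–receptor stage finds exactly one interface-enriched pair, the
planted one:

```r
res$lr$enrichment[res$lr$enrichment$fisher_p_adj < 0.05, ]
#>    ligand receptor     interface n_active_here n_active_elsewhere fisher_p_adj
#> 13 gene111 gene112 focal|region4             2                  0       0.0385
```

Every stage writes a TSV under `out_dir` (plus `manifest.json` with
seeds, parameters and timings); reruns with the same configuration are
byte-identical.

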