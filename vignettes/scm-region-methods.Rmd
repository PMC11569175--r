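---
title: "Calling and characterizing cell-state mapping regions in spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing cell-state mapping regions in spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmregions)
```

# Overview

`scmregions` analyses the tissue microenvironment in 10x Visium spatial
transcriptomics starting from per-spot cell-state abundance estimates, the
kind of output a deconvolution model produces when it maps a single-cell
reference onto spots. The pipeline has five analytic stages:

1. **Region calling** — iterative non-negative matrix factorization (NMF)
   over the spots-by-states abundance matrix with a component-uniqueness
   stopping rule; each spot is assigned to its highest-contributing
   component. We call the resulting tissue domains single-cell-mapping
   (SCM) regions.
2. **Region markers** — per-sample one-vs-rest Wilcoxon differential
   expression, combined across samples by a one-sided Fisher
   meta-enrichment that declares genes recurrently overexpressed in a
   region its *region-specific markers*.
3. **Spatial structure** — hexagonal-lattice neighbourhood graphs,
   permutation neighbourhood-enrichment z-scores, and the
   proximal/distant/interface annotation of spots around a focal region.
4. **Signature scoring** — gene-set activity scores with
   expression-bin-matched control genes, quantile-effect-size group
   comparisons, and region-fraction versus score correlations.
5. **Ligand-receptor testing** — a permutation test of pair co-expression
   across region interfaces, with a cross-sample Fisher test for
   interface-specific enrichment.

A synthetic cohort generator with full ground truth makes every stage
testable without any external data.

# The region-calling model

Let $A \in \mathbb{R}_{\ge 0}^{n \times S}$ hold the inferred abundance of
$S$ cell states in $n$ spots pooled over all samples. For each component
count $k$ in a range (default $5\dots12$) we fit
$A \approx W H$, $W \in \mathbb{R}_{\ge 0}^{n\times k}$,
$H \in \mathbb{R}_{\ge 0}^{k\times S}$, minimizing the Frobenius objective
$\tfrac12\lVert A - WH\rVert_F^2$ by multiplicative updates from an NNDSVD
initialization (zeros replaced by a small constant so updates never lock).
For each component $j$ the *top state* is
$\arg\max_s H_{js}$. A $k$ is admissible when all $k$ top states are
distinct; the chosen model is the **largest admissible $k$** — the most
granular partition in which every component is still anchored by its own
cell state. If no $k$ in the range is admissible this is an error carrying
the per-$k$ duplicate states, never a silent fallback. Spots are labeled by
$\arg\max_j W_{ij}$, with exact ties broken to the lowest component index
(deterministic; ties are measure-zero in practice) and all-zero rows
reported as unassigned.

Numerical choices: maximum 2000 iterations, convergence when the relative
objective decrease falls below $10^{-6}$ (checked every 10 iterations), and
abundances enter the factorization unscaled — spot argmax labels are
invariant to positive per-spot scaling anyway, and a per-spot
sum-normalization option would only change the factors, not the selection
rule on well-separated data. The NMF is deterministic given the data; the
`seed` argument only affects a random fallback used if the SVD rank is
insufficient for the requested $k$.

# Region markers

Within each sample, each region with at least 10 spots is compared to all
other spots of that sample gene-by-gene with a two-sided Wilcoxon rank-sum
test. Mitochondrial and ribosomal genes (symbols matching `^(MT-|RPL|RPS)`,
configurable) are excluded. P-values are Benjamini-Hochberg adjusted within
the (sample, region) family, and a gene is *differentially expressed* (DE)
when $\log_2\mathrm{FC} \ge 1$ and $p_{adj} < 0.05$. The fold change is
computed between linear-scale group means of `expm1(normalized)` with
$\varepsilon = 10^{-9}$, so the printed threshold of 1 has the conventional
meaning. When group sizes are small enough that the full set of
group assignments can be enumerated (at most 20000 combinations), the
rank-sum p-value is exact by permutation enumeration, which handles ties
correctly; otherwise a tie-corrected normal approximation with continuity
correction is used.

The meta-analysis counts *instances* — (sample, region) pairs that were
actually tested; regions dropped by the 10-spot floor are untested, not
non-DE, which changes the margins of the table below and is therefore
stated explicitly. For gene $g$ and region $r$ the $2\times2$ table

|              | DE          | not DE      |
|--------------|-------------|-------------|
| instances of $r$      | $a$ | $b$ |
| instances of other regions | $c$ | $d$ |

is tested one-sided (greater) with Fisher's exact test, computed as the
hypergeometric tail. BH adjustment runs within each region across genes —
matching the per-region marker lists the analysis reports — and a gene with
$p_{adj} < 0.05$ is a region-specific marker; a gene may mark several
regions. Category-wise differential expression inside one region
(e.g. treatment-naive versus neoadjuvant-treated samples) pools the
region's spots per category and applies the same rank-sum/BH/fold-change
machinery pairwise. Gene-set overrepresentation among markers is again a
one-sided Fisher test over the tested-gene universe.

# Spatial structure

Visium spots form a staggered hexagonal lattice: valid array coordinates
satisfy row + col even, and the map $q = (col - row)/2$, $r = row$ takes
them to axial hex coordinates where distance is
$(\lvert\Delta q\rvert + \lvert\Delta r\rvert + \lvert\Delta q + \Delta
r\rvert)/2$ — the shortest-path length on the 6-neighbour graph. One ring
corresponds to roughly 100 µm centre-to-centre; all neighbourhood analyses
use rings $\le 3$ (about 300 µm).

**Neighbourhood enrichment.** For every region pair we count spot pairs at
ring distance $\le 3$ joining the two regions and compare against the same
count under random permutations of the labels over spots (default 1000):
$z = (\mathrm{obs} - \mu_{null})/\sigma_{null}$, with $z \equiv 0$ when the
null is degenerate (e.g. a single-region sample). Cohort summaries average
per-sample matrices after zeroing rows/columns of regions missing from a
sample. All edges with $d \le 3$ count equally.

**Proximity and interfaces.** A focal-region spot is *anchored* when at
least one ring-1 neighbour shares its label; isolated spots are *sporadic*
and never generate proximity. A non-focal spot is *proximal* when it lies
within 3 rings of two anchored focal spots that are adjacent to each other,
else *distant*. The phrase "two or more adjacent focal spots" admits a
second reading — any two anchored spots, not necessarily mutually adjacent
— and both are implemented behind the `rule` flag; pair-adjacency is the
default because the rule exists to exclude lone sporadic spots, which a
lone spot can never satisfy. Samples with fewer than 10 focal spots are
excluded outright. For a region pair (F, G), a spot of F is *interacting*
when it is anchored in F and at least 2 G-spots lie within 3 rings; the
interface exists in a sample only when both interacting sets have at least
10 spots.

# Signature scoring

Genes are placed into 25 equal-frequency bins by mean normalized expression
(ties broken by gene name, so the binning is order-invariant). For every
bin containing a set gene, 50 control genes are drawn without replacement —
the whole bin when it is smaller. No gene is excluded from the control
pool, so set genes may serve as their own controls; the score of a spot is
the mean normalized expression of the set minus the mean over the pooled
controls. Two consequences worth knowing: a constant matrix scores exactly
zero, and a set that covers whole bins is exactly self-controlled. When the
set is small relative to the bins (the intended regime: tens of genes
against a transcriptome), a planted additive shift $\delta$ on the set
genes is recovered to within a few percent; with very small transcriptomes
the set contaminates its own control bins and the score shrinks towards
zero — the package does not correct for this, matching the cited scoring
convention.

Group comparisons report a Welch two-sided t-test plus a quantile effect
tier: `***` when the comparison group's 90th percentile lies below the
focal mean, `**` for the 80th, `*` for the 70th (each also requiring
p < 0.05). The tiers nest by construction. The region-fraction correlation
analysis pools all non-focal spots cohort-wide on raw counts, drops genes
expressed in fewer than 10 samples (capped at the cohort size for small
cohorts), renormalizes, scores, summarizes each sample by its mean
non-focal score, and reports the Spearman correlation with the per-sample
focal-region fraction; degenerate constant inputs report $\rho = 0$ with a
warning rather than NA.

# Ligand-receptor testing

Pairs with fewer than 3 literature references are discarded up front. At an
interface, a pair is tested only when the ligand is detected in more than
1% of the F-side interacting spots and the receptor in more than 1% of the
G-side spots; gated-out pairs are *untested*, not $p = 1$. The statistic is
the mean of the two side means of normalized expression; the null permutes
the side assignment over the union of interacting spots (default 1000
permutations). The p-value uses the add-one estimator
$(1 + \#\{null \ge obs\})/(1 + B)$, so the smallest attainable value is
$1/(B+1)$ and the test is never anti-conservative at zero — a deliberate
deviation from implementations that report 0. The test treats the two
directions symmetrically in distribution; because permutation subsets are
resampled per call, a direction swap reproduces the p-value up to Monte
Carlo error (and exactly at the attainable minimum). BH families are per
(sample, interface, direction); pairs with $p_{adj} < 0.05$ are *active*.
Interface-specific enrichment compares, for each pair, active versus
tested-not-active counts at one interface type against all others with a
one-sided Fisher test, BH-adjusted across pairs within the interface type.
Multi-subunit complexes are not modeled; rows naming complexes should be
expanded to subunit pairs upstream.

# Preprocessing contract

Per sample: genes detected in fewer than 5 spots are dropped (computed on
the raw matrix), then spots with fewer than 500 UMIs — strict inequalities,
in that order. Normalization scales each spot to the median spot total and
applies log1p. This median-library-size contract replaces pooling-based
size-factor normalization deliberately: every downstream test is rank-based
or bin-matched and thus insensitive to monotone per-spot scaling, the
contract is exactly reproducible, and the normalization entry point is a
single function that can be swapped.

# The synthetic cohort generator

The generator emulates the study design the pipeline targets: a cohort
spanning benign (BPH), treatment-naive (TRNA), neoadjuvant-treated (NEADT)
and castration-resistant (CRPC) categories, by default 3 sections each on
30 x 30 staggered lattices (900 spots), 26 cell states of which 8 drive
latent regions, and 1000 genes.

* **Region fields** grow from random seed spots by randomized
  breadth-first accretion, giving spatially coherent single-patch regions
  (mean ring-1 label agreement well above 0.6).
* **Abundance**: spot $i$ in region $r$ loads state $r$ with
  $0.6 + \Gamma(2, 0.35)$ inferred cells, one of two region-specific
  companion minor states with half that loading (chosen per spot), and
  $0.05\,\mathrm{Exp}(1)$ noise on every state, then scales to about 20
  cells per spot. The companion construction mirrors real deconvolution
  output, where low-abundance states co-vary with the major compartments,
  and it pins down the uniqueness rule's stopping point: a component count
  beyond the true number of regions can only split a region into its two
  companion subprofiles, which share the dominant state and therefore
  collide. The noise scale keeps over 95% of spots argmax-correct.
* **Counts** are negative binomial (variance $\mu + \mu^2/\phi$, $\phi=2$
  — stated because the emulated study has no generative model at all) with
  a shared Gamma baseline per gene, log-normal library sizes around 2000
  UMIs, 10 disjoint marker genes per region at $2^{2}$-fold inside their
  region, a planted signature set shifted $2^{0.5}$-fold in the club-like
  region, and an AR-like set expressed high at baseline and suppressed
  four-fold in NEADT/CRPC samples while club-like markers stay flat —
  minimal, signed, known category effects rather than an attempt at full
  biology.
* **Ligand-receptor planting** inflates the planted ligand in source-region
  spots within 3 rings of the target region and the receptor in
  target-region spots within 3 rings of the source ($2^{3}$-fold), so the
  planted co-expression is specific to that interface band. The planted
  genes get a fixed moderate baseline so the contrast is a clean known
  quantity.
* A single cohort seed drives everything; per-sample substreams sit at
  fixed offsets, so extending a cohort never perturbs existing samples.
  Count-space category effects do not transfer exactly into log-space
  score shifts at low counts, so score-recovery calibrations plant an
  additive shift directly on normalized values instead.

What the generator does **not** emulate: spot swapping and transcript
bleed, doublets and segmentation error, batch effects between samples,
histology images, or the full correlation structure of a real
transcriptome. Passing tests therefore demonstrate that the algorithms
implement their definitions and recover planted truth under realistic
noise — not that any biological conclusion transfers to a particular
tissue.

# Verification scales

The test-suite and acceptance-script simulations were sized so that each
property is measured with adequate power while the whole suite stays quick
to run: region recovery on the full 12-sample, 900-spot-per-sample cohort;
marker calibration on 8-sample cohorts of 12 x 12 lattices and 120 genes
(100 null cohorts for the false-marker rate); neighbourhood-enrichment
calibration on 200 replicate 10 x 10 samples with 300 permutations;
interface-annotation agreement against a brute-force oracle on 50 random
12 x 12 labelings; and 500 background pairs for the ligand-receptor null.
These sizes are the package's verification conditions, stated here so they
can be reproduced or scaled up.

# Known limitations

* The uniqueness stopping rule presumes the abundance matrix has more
  states than tissue domains and that domains are anchored by distinct
  dominant states; on data violating this (e.g. two domains dominated by
  one state) it correctly refuses to select a model rather than guessing.
* The hex machinery is Visium-specific; no arbitrary-geometry or
  micrometre-distance mode is provided (rings only).
* Wilcoxon DE on spots ignores within-sample spatial autocorrelation, as
  does the scoring; the meta-enrichment across samples is the guard
  against sample-level artefacts.
* Single-gene ligand/receptor partners only; no curated LR database is
  shipped beyond the synthetic demo table.

# A short run

```{r, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 7), seed = 7)
res <- run_pipeline(cfg, out_dir = "run")
res$model            # chosen k and top states
head(res$markers$markers)
res$lr$enrichment
```
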