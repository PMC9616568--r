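---
title: "Methods: quantifying projection-neuron organization and its synaptic readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying projection-neuron organization and its synaptic readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnorg)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the design
choices made where the published procedure left the design open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model of the data

A uniglomerular projection neuron (uPN) is represented by its SWC skeleton:
a rooted tree (or, for fragmented EM reconstructions, a forest — accepted
with a warning) of 3-D points in micrometres. The analysis population is
restricted to uPNs that innervate all three olfactory neuropils — antennal
lobe (AL), mushroom body (MB) calyx, lateral horn (LH) — because every
statistic is compared across neuropils per neuron. Annotations attach a
glomerulus label (homotype), an odor-type category (10 closed categories), a
putative valence (attractive / aversive / unknown; the packaged fixture
carries the published 17 attractive and 25 aversive homotypes) and a tract.
The community glomerulus renaming VC3l→VC3, VC3m→VC5, VC5→VM6 is applied as
a simultaneous (non-cascading) map, on by default.

Units are always micrometres internally. The raw unit of an SWC export is
dataset-specific (nanometres for FAFB/CATMAID exports, voxels for
hemibrain), and no universal conversion can be assumed, so `read_swc()`
requires an explicit `unit_scale` (e.g. 0.001 for nm). Every downstream
distance is exactly linear in this scale, which the test suite asserts.

## Neuropil segmentation

Neuropils are node-dense; the tracts joining them are thin. Projecting the
pooled point cloud onto an axis therefore yields a density profile whose
deep local minima sit between neuropils. Because a single fixed axis cannot
always separate all three regions, the cloud is rotated about the reference
axes on a 5° grid (one axis at a time; whether the original search was joint
or per-axis is unspecified, and the per-axis search is cheaper and
sufficient on separable scenes) and the rotation minimising
`mean + weight·sd` of the density at the qualifying minima is kept
(`weight = 1`; the published criterion uses both the average and the
deviation without stating their combination, and equal weighting is the
neutral choice).

Numerical choices the source is silent on, fixed here once:

* histogram bin width 2 μm with Gaussian smoothing at one-bin bandwidth —
  raw EM node histograms are noisy at finer bins;
* minima are *plateau-aware* (a run of constant density between two higher
  runs counts once, at its centre) because evenly spaced backbone nodes
  produce exactly constant-density gaps that strict neighbour comparisons
  would miss;
* a minimum qualifies only with topographic prominence ≥ 5% of the profile
  maximum;
* boundary conditions use half-open, lower-closed intervals `[lo, hi)`, so a
  node exactly on a cut belongs to the upper region deterministically.

`segment_scene()` automates the common tri-modal case: it takes the three
tallest plateau-aware peaks as the neuropil modes, cuts at the lowest
profile point between consecutive modes, and trims each interval to the
occupied density support (≥ 5% of maximum) so deep gaps stay unassigned.
Users can bypass the scan entirely with explicit `segmentation_rule()` sets
or precomputed masks, mirroring the visual-inspection confirmation step of
the original procedure. On separable generator scenes the masks recover the
planted region membership of every arbor node exactly; backbone connector
nodes adjacent to a region are swept into its flanking interval, which is
the documented tolerance (they are genuinely continuous with the arbor).

## The inter-PN distance

For point sets with N~α~ ≤ N~β~,
d~αβ~² = (1/N~α~) Σ~i~ min~j~ ‖r~i~^α^ − r~j~^β^‖². Properties relied on
downstream, all property-tested: non-negativity with equality exactly on
subset coincidence; invariance under a common rigid motion; exact
covariance under scaling; symmetry via the smaller-set convention. When
N~α~ = N~β~ the two orientations can differ; the scalar function uses its
first argument as reference, and the matrix builder fixes the tie by taking
the lexicographically smaller neuron id as reference, so results never
depend on input order. d~αβ~ violates the triangle inequality in general —
the clustering stage makes no metric assumption. No node resampling is
applied before the computation (the published analysis used raw
reconstruction points); node-density bias is therefore inherited, which is
the faithful behaviour.

## Homotype statistics

d̄~intra,X~ averages d~αβ~ over unordered within-homotype pairs (each pair
once; the normalising N is read as the pair count), d̄~inter,X~ over all
cross pairs, λ~X~ is their ratio. Single-uPN homotypes get an undefined
d̄~intra~ and λ (flagged `*`), and are excluded from every population
average — the asterisk convention. This exclusion automatically propagates
to the cross-neuropil λ correlation (Pearson r with a two-sided t-test),
resolving in the strict direction the open question of whether those
homotypes were excluded there. The λ = 0.4 bundling threshold is
descriptive, not fitted; it is exposed as `lambda_threshold`.

## Spatial clustering

Complete linkage (`stats::hclust(method = "complete")`) builds the
dendrogram; its monotone heights are what the cut relies on. The default cut
is a **dynamic hybrid tree cut** with minimum cluster size 4. The cited
implementation of that method is not available in this environment, so the
package authors its own, keeping the method's contract: each branch is
decomposed at the largest multiplicative gap in its sorted merge heights
(bundle-internal merges are small, junction merges large); a gap counts as a
junction when consecutive sorted heights jump by ≥ `ratio`, with `ratio`
mapped from `deep_split` 0..4 as 4, 3, 2.2, 1.8, 1.5 (default `deep_split =
2`). A cut is only accepted when it produces at least two components of at
least `min_cluster_size` leaves — this guard is what prevents a tight
bundle from being shredded into fragments. Undersized branches are
dissolved and their leaves assigned, PAM-like, to the qualifying cluster
with the smallest mean dissimilarity (ties to the lower cluster index). The
whole procedure is deterministic given the tree. Exact numerical agreement
with the original dynamic-tree-cut software is *not* claimed; planted-bundle
recovery in the separable regime is what the acceptance suite verifies
(adjusted Rand ≥ 0.95).

The alternative criteria follow their standard definitions on partitions
from `cutree`: elbow = maximum second difference of the pooled
within-cluster dispersion W~k~ = Σ~r~ D~r~/(2n~r~) (squared distances); gap
statistic with B = 50 uniform reference draws over the data bounding box
(seeded) and the usual one-standard-error rule; silhouette = k maximising
the mean silhouette width over k = 2..k_max. The k search range defaults to
min(60, n−1); the published silhouette value of 54 clusters for AL implies
an unusually wide search range whose bounds were unstated — flagged, not
guessed.

## Association tests

Pearson χ² with expected counts from the product of the margins, no
continuity correction, upper-tail p on (R−1)(C−1) degrees of freedom. A
zero margin is an error rather than a silent drop. Bias-corrected Cramér's
V uses φ′² = max(0, χ²/N − (R−1)(C−1)/(N−1)) with the R′, C′ corrections.
Mutual information is the plug-in estimator in natural log (the source
writes an unqualified log; nats are the convention fixed here), with
0·log 0 = 0. Its significance comes from permuting *one* label vector
(permuting the second suffices; permuting both adds nothing to the null)
1000 times, with the add-one correction p = (1 + #{I ≥ I_obs})/(n_perm + 1)
so p is never exactly zero; significance is declared at α = 0.01.

**A discrepancy, kept honest.** The packaged 3×10 valence-by-MB-cluster
contingency table (shipped verbatim as printed, margins 44/47/44 by row and
N = 135) yields χ² = 62.57, p = 7.8×10⁻⁷, bias-corrected V = 0.409. The
originally reported values for this table are χ² ≈ 66.1 and
p ≈ 2.016×10⁻⁷ — a pair that is internally consistent (the quantile of 66.1
at 18 dof reproduces that p) but not consistent with the printed table
under any variant we tried (G-test, totals-included table). The package
computes faithfully from the printed counts and does not adjust the fixture
to chase the reported statistic; the corresponding acceptance assertions
are intentionally left failing as a record of the discrepancy.

## Synaptic interfaces

The synapse threshold (default N = 3; N = 8 as the stringent robustness
setting) applies per (uPN, partner) pair, and a partner column is retained
only if some pair meets it — the partner-inclusion rule. At homotype level,
C~X,i~ = 1 when any member uPN of X meets the threshold with partner i.
N~X,tot~ is the row sum; N~X,sp~ counts partners whose column sum is 1;
S~XY~ counts shared partners (computed by explicit counting and checked
against the C·Cᵀ oracle in the tests). Raising the threshold can only
remove edges, so N~tot~ and S are non-increasing from N = 3 to N = 8 —
asserted as a property; N~sp~ may move either way and is not constrained.

Connectivity-based clustering operates on *per-uPN* binary rows (the S
matrices live at homotype level; the two levels are kept explicit), with
cosine distance 1 − u·v/(|u||v|) and Ward linkage (`ward.D2`, the
variance-minimising update on the given dissimilarities). Congruence
between the spatial and connectivity dendrograms is scored by Baker's Γ
(Spearman correlation of first-co-clustering levels over leaf pairs),
entanglement after one-sided `step1side` untangling — tree 1's leaf order is
fixed and tree 2's internal nodes are greedily rotated towards it by mean
target rank; the score is the sum of squared leaf-rank differences
normalised by the fully reversed order — and the Pearson correlation of
cophenetic matrices. A full two-sided untangling search is out of scope.
The statistical calibration of these indices is provided as a seeded
permutation null over leaf relabelings with the same add-one p-value,
standing in for a calibration whose original definition was not available.

## The synthetic world

`generate_population()` states the world the tests live in: three regions
of radius 10 μm with centres 60 μm apart along x (gaps ≫ spreads — the
"separable" regime is asserted and violating specs are an error); per
region, each homotype owns an anchor, by default evenly spaced on a circle
of radius `anchor_spread` (deterministic inter-homotype separation; a
uniform-ball mode exists); each neuron adds one constant lateral offset
drawn at scale σ (the intra-bundle spread, the generator's main dial,
σ ≈ 1–8 μm spanning the observed λ range) and arborises as a Gaussian cloud
(sd 1 μm, ~25 nodes) around each anchor, joined by backbone nodes every
2 μm. Arborisation is a point cloud, not a realistic branched tree, because
every statistic in scope is a point-cloud functional; a nearest-neighbour
branching mode exists for SWC realism. Ground truth (per-node region,
per-neuron homotype) and the full parameter manifest are emitted alongside.

What a green test on this world establishes: the estimators recover planted
bundling (λ monotone in σ, Spearman 1 over 5 levels × 10 seeds), planted
clusters (ARI ≥ 0.95), planted region membership (exact on arbor nodes) and
planted connectivity specificity (exact below threshold). What it does not
establish: robustness to reconstruction breaks, node-density gradients,
realistic arbor geometry, or boundary ambiguity between touching neuropils
— none of which the generator emulates.

`generate_synapses()` plants connectivity ground truth exactly: each
homotype receives `round(specific_fraction · n_partners)` exclusive
partners; remaining slots are filled by shared partners that are always
wired to ≥ 2 homotypes (so measured N~sp~ equals the planted count
exactly); optional blocks wire homotype cliques to common partners
(emulating food-odor-style co-integration); weights are shifted-geometric
counts (support ≥ 1, configurable mean), and uPN-level expansion keeps each
homotype edge realised by at least one member.

## Pipeline determinism and limits

All stochastic stages derive their seeds from the single configured seed;
two runs with the same config produce byte-identical outputs, and a rerun
with an unchanged config is a no-op via a content hash of the configuration
(output paths excluded from the hash). Stage subcommands execute the same
code path as the composed pipeline, which is what makes their outputs
bit-identical. Known limitations: the dynamic hybrid cut is sensitive to
the junction/bundle height ratio near its `deep_split` threshold (scenes
whose separations barely exceed bundle diameters may merge or split
marginally — visible when σ approaches the anchor spacing); the gap
statistic needs raw coordinates, not just a distance matrix, for its
reference distribution; and the `reproduce-paper` CLI subcommand only
scripts the external re-analysis and requires user-downloaded FAFB/
hemibrain exports, so it is excluded from all tests.
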