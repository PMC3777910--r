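---
title: "Methods: quantifying regional specialization of the developing brain transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying regional specialization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regiospec)
```

# The model

The package treats a developing brain as a gene x region x timepoint tensor
of expression densities (the fraction of expressing signal per anatomical
region, as quantified from in situ hybridization; the package consumes
these densities, it does not compute them from images). All statistics are
built on one primitive: the dissimilarity between two regions at one age is
`1 - PCC`, one minus the Pearson correlation of their expression vectors
across genes. Pearson correlation is location- and scale-invariant, so the
statistic is insensitive to region size and overall staining intensity, and
ranges over `[0, 2]` with 1 meaning uncorrelated and 2 perfectly
anti-correlated profiles.

Three assumptions are worth making explicit. First, regions measured at an
age are comparable: the density normalization has removed size effects.
Second, the gene panel is informative for regional identity; the robustness
procedures (random subsets, variable-gene removal, leave-one-region-out,
ontology-level aggregation) probe how much any conclusion depends on the
particular genes and regions. Third, ages are an ordered categorical axis:
no arithmetic is done on age labels, and the quadratic fit to the curve
uses the ordinal rank (0, 1, 2, ...) as its abscissa, matching the
categorical spacing of the time course.

## Gene contributions and functional enrichment

The contribution of gene `g` at age `t` is `deltaD_g(t) = Dbar(t) -
Dbar_without_g(t)`, where `Dbar` is the mean over region pairs and the
leave-one-out term is recomputed from scratch on the gene-deleted data, on
identical region masks. No incremental update shortcuts are used — an
explicit design choice so that every value equals its brute-force
definition to floating-point accuracy, which the tests assert at 1e-12.
Contribution profiling is meant for the developmental ages; an adult
endpoint, when present, can be excluded via the `timepoints` argument.

Profiles are clustered with k-means over the grid `k = 10, 15, ..., 50`
(nine values), Euclidean metric on the raw profiles — standardizing would
erase the contribution scale, which is the signal. Initialization is
k-means++-style seeding with Lloyd iterations, 10 restarts per `k`, best
within-cluster sum of squares kept; all restarts derive from one seed.

Cluster enrichment uses the exact upper-tail hypergeometric test against
the clustered-gene universe, restricted to categories with at least 10
annotated genes (and optionally to a domain whitelist). Multiple testing is
handled by a two-stage FDR: Benjamini-Hochberg across all
(cluster, category) tests within each clustering, then, per category, BH
across the k grid, where each `k` contributes the category's minimum
stage-1 q over clusters. The minimum-over-clusters summary was an open
choice (each category "receives one value per k" admits several readings);
the minimum is natural because a category is called through its best
cluster, and the raw-p variant is available via `stage2Input = "p"`. Both
stages pool across clusters x categories within a family — the larger, more
conservative family. A category is reported enriched when its smallest
stage-2 q falls below 0.01, and a GO-hierarchy screen then drops any
enriched category with an enriched strict descendant of lower q, keeping
the most refined terms.

Phase calls compare a cluster's pooled contribution values over embryonic
ages (E11.5-E18.5) against postnatal ones (P4-P28) with the two-sample
rank-sum test at 0.05, labelling the side with the larger median. The
pools are unpaired and of unequal size (4 vs 3 ages x cluster genes), so
the two-sample form is the defined choice here; a paired signed-rank test
has no meaning for such pools.

## Region-level analysis

A region's specialization index is its mean dissimilarity to all other
regions divided by the overall pair mean; averaged over regions the index
is 1 by construction, so values above 1 flag regions more distinct than
the brain-wide average. Embeddings use non-metric MDS (Kruskal stress-1,
vegan's global model) started from the classical metric solution plus
seeded random restarts (10 starts, 500 iterations, stress tolerance 1e-10);
on distance matrices exactly realizable in the plane this reaches stress
below 1e-6. Configurations are aligned chronologically by Procrustes
(translation, rotation/reflection, isotropic scaling; the closed-form SVD
optimum; disparity = residual sum of squares over the centred reference's
sum of squares), each age to the previous aligned one, so developmental
trajectories read continuously. Missing dissimilarities are imputed by the
matrix maximum before embedding — a conservative choice that keeps
unmeasured pairs maximally separated, and is logged.

Lineage structure is scored as the Pearson correlation, per age, between
pairwise dissimilarity and the path distance of the regions' embryonic
origins on a fixed four-leaf lineage tree (telencephalon and diencephalon
under a forebrain node; midbrain; hindbrain; unit branch lengths; distance
0 for shared origin). The tree is the simplest one consistent with the
three embryonic vesicles and the forebrain split; any monotone relabelling
of its distances would change `r` only slightly since only four distinct
values occur.

## Gene families and cross-species comparison

Family membership is scored by global Needleman-Wunsch alignment under
BLOSUM50 with a linear gap penalty of 8 per gap symbol (no separate
opening/extension costs), score >= 0 declaring a match; the implementation
delegates the dynamic program to Biostrings and the tests verify scores
against an independent exhaustive-recursion oracle. Spatial correlation of
a pair is the Pearson correlation of their regional patterns at the two
peak-dissimilarity ages; matched pairs with correlation beyond +/-0.2 are
stratified as similar-correlated or similar-anticorrelated.

Cross-species matrices compute, for every (source age, target age) pair,
the Spearman correlation over ortholog genes of averaged region-set
profiles, averaged over mapped region pairs. Averaging the per-pair
correlations (rather than correlating species-averaged profiles) preserves
region-specific signal; the alternative is available via
`average = "profiles"`. Ties get average ranks; orthologs missing at a
given age/region are dropped pairwise.

# The synthetic generator

The generator is the package's test bed: it emits datasets whose structure
is known exactly, so every downstream stage can be checked against ground
truth. Its defaults are the study conditions used throughout the tests:
200 genes x 12 regions x 7 ages, a U-shaped envelope of region-specific
signal (high at the ends of the time course, near zero mid-series), 30%
"construction" genes whose regional signal follows the declining embryonic
limb, 30% "plasticity" genes following the rising postnatal limb, the rest
null; four lineage blocks; one planted GO category per program (20 genes)
plus ten random distractor categories of the same size as a calibrated
null; four paralog pairs at target spatial correlation -0.6; Gaussian noise
(sd 0.1 on the density scale) with clipping at zero. Gaussian noise with
clipping is the simplest model preserving non-negativity; real ISH
densities have heavier tails and spatial artefacts that this does not
emulate, so passing tests demonstrate correctness of the statistics, not
robustness to atlas-specific noise.

Design choices that were genuinely open:

- **Lineage blocks as gene loadings.** A scalar offset added to all genes
  of a region cannot plant lineage structure, because Pearson correlation
  is invariant to adding a constant to a region's vector. Blocks therefore
  share a per-block random *gene loading* (sd 0.25, constant over time),
  which makes same-origin regions genuinely more correlated at every age.
- **Paralog planting is empirical, not distributional.** The second
  loading of a pair is constructed by orthogonalization and mixing so its
  *sample* correlation with the first equals the target exactly; the
  realized expression correlation then deviates only by noise attenuation
  and clipping (within about 0.1 at 30 regions).
- **Planted categories carry an amplified loading.** Planted-category
  genes get their region loading scaled by 2. Without this, a 20-gene
  category is a random subset of a 150-gene program whose members spread
  over several k-means clusters, and no cluster is enriched — the planted
  signal must be a coherent *profile cluster*, not merely a program
  subset.
- **The breakaway region ramps geometrically.** Driver genes (15, positive
  loadings) on the breakaway region have amplitude multiplied by 3.6 at
  each successive postnatal age from a base of 0.15. The normalized
  specialization index divides by the brain-wide mean dissimilarity, which
  itself rises steeply after birth; a divergence that grows only linearly
  is overtaken and the index stalls. The geometric ramp keeps the region's
  relative excess growing through the final age without saturating the
  dissimilarity ceiling (d <= 2) earlier.
- **Counterpart warping.** The second-species generator maps each source
  age to a strictly increasing integer target position; target ages
  between mapped positions are linear interpolations of the flanking
  sources. The counterpart grid spans exactly the warp's range so that, at
  zero noise, each source age has a unique exactly-matching target age and
  the Spearman ridge recovers the warp without ties.

# Numerical choices and degenerate inputs

Missing measurements are explicit `NA`s; correlations use pairwise-complete
genes, pairs with fewer than 3 common genes or a zero-variance vector are
missing entries (not errors), and a fully complete slice takes a single
matrix-correlation fast path that is algebraically identical to the
pairwise kernel. The quadratic fit requires 3 non-missing curve points.
BH q-values use the standard monotone step-up. k-means tie-breaking and
restart selection are fully determined by the seed. Needleman-Wunsch
traceback prefers diagonal, then up, then left. Expression files use UTF-8
TSV with `%.17g` numeric formatting so write/read/write cycles are
byte-identical.

# Problem sizes in the test suite

The tests run the oracle-equivalence checks on 30 x 8 x 5 tensors, the
hourglass and cross-species recovery on the default 200 x 12 x 7
conditions over 20 generator seeds, enrichment power on 500-gene universes
over 20 seeds and calibration over 50 seeds, and breakaway recovery on
100 x 10 x 7 tensors over 20 seeds. These sizes keep the full suite to a
few minutes while leaving each statistic comfortably in its asymptotic
regime.

# Known limitations

The generator's noise model is additive Gaussian with clipping, not a
density-derived binomial or image-artefact model. Missingness in real
atlas exports is structured (whole regions absent at early ages); the
generator omits cells only if asked, and the analysis treats missingness
as ignorable within each pairwise correlation. The lineage tree is fixed
and four-leaved; finer origin taxonomies would need a user-supplied
distance. The enrichment machinery assumes one annotation universe — the
clustered genes — and does not model annotation bias. None of the
package's outputs are corrected for spatial autocorrelation between
adjacent regions, which real atlases exhibit and the generator does not.
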