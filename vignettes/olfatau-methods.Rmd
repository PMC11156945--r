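---
title: "Methods: olfactory dysfunction, tau accumulation and spreading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: olfactory dysfunction, tau accumulation and spreading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfatau)
```

# Scope and scientific setting

`olfatau` implements an analysis pipeline linking odor-identification
performance in cognitively normal older adults to regional tau accumulation
and its longitudinal spreading. The stages are:

1. **Normative aging curve** — a robust (RANSAC) quadratic fit of the
   40-item smell-identification composite (UPSIT, 0–40) against age, with
   per-subject deviation scores and per-odorant identification rates.
2. **Voxel-wise association mapping** — mass-univariate GLMs of tau SUVr
   (or grey-matter density, amyloid DVR, mean diffusivity) volumes against
   olfactory predictors, with two bespoke Monte-Carlo corrections: a
   *cluster-extent* null and an *odorant-count* null.
3. **PCA odorant biomarkers** — a bipartite 40-odorant × voxel matrix of
   association Z statistics, reduced by PCA over the odorant dimension to
   weight vectors ("olfactory dysfunction" biomarkers), subject scores, and
   back-projection of those scores to corrected voxel maps.
4. **Along-tract statistics** — skeletonization of a tract mask into 100
   equal-length segments, per-segment mean-diffusivity profiles, and a GLM
   of each segment against the smell composite.
5. **Directional spreading graph** — for every ordered region pair, the
   partial correlation of *baseline* tau at the source with *follow-up* tau
   at the target, conditioned on baseline tau at the target (plus
   covariates), giving an asymmetric "tau connectivity" matrix; weighted
   in/out degrees summarize sources and receivers.
6. **Conditional-independence backbone** — the skeleton phase of the PC
   algorithm on baseline values prunes indirect connections; arrows are
   drawn from the bipartite graph's significant directions.
7. **Gene co-expression** — region-level transcriptome processing (donor
   means, cross-donor medians, per-gene z-scoring), Pearson co-expression,
   agglomerative clustering with silhouette-selected k, hemisphere-z-scored
   cluster maps, and gene–trait bipartite networks weighted by best GWAS p.

The cohort data this design targets are access-restricted, so the package
ships first-class synthetic generators (`cohort_spec()`, `spread_truth()`,
`tract_phantom_spec()`, `expression_truth()`, `generate_rank_one_study()`)
that emulate the relevant statistical structure with known ground truth.
Every stage is validated by recovering what the generators plant.

# The synthetic cohort

`generate_cohort()` draws ages (truncated normal, mean 72, SD 8.3 within
50–90 years by default), binary sex/APOEε4/smoking covariates, years of
education, and an inter-scan interval (normal, mean 2.38, SD 0.45 years) at
the demographic rates typical of aging cohort studies. The mean composite
follows a quadratic age trend (default `5.75 + 1.1*age - 0.01*age^2`: a
plateau near 36/40 in the mid-fifties with accelerating decline beyond the
seventh decade) plus covariate effects, Gaussian noise (SD 2 points), and a
planted fraction (default 5%) of gross outliers shifted by −15 points —
subjects whose odor identification is far below their age norm.

Two response models turn a subject's composite target into 40 binary item
responses:

* **`"quota"` (default).** The subject identifies the `target` easiest
  odorants under a logistic perturbation of the item difficulties
  (a Thurstonian ranking model). The composite equals its target exactly,
  so the composite-level invariants are exact: in the noise-free limit every
  composite equals the rounded quadratic trend. Items correlate through the
  shared target, as real items correlate through a subject's overall
  olfactory ability.
* **`"independent"`.** Items are independent Bernoulli draws with
  probability `plogis(logit(trend/40) − centered difficulty)` — responses
  are conditionally independent given age and covariates. This is the
  regime in which the 40 per-odorant association maps are mutually
  independent under the null, which is exactly what the odorant-count
  Monte-Carlo null assumes; calibration studies of that correction use this
  model.

The distinction matters: with strongly correlated items the count
correction's independent-map null is anti-conservative by construction
(this is a property of the method, not of the implementation), so the
family-wise calibration study must be run in the model that satisfies the
null's assumptions. Both models satisfy `upsit = sum(responses)` and
`0 ≤ upsit ≤ 40` exactly.

Item difficulties default to an even spread giving identification rates
from ~95% down to ~55%, matching the observed range from easy odorants
(onion, peanut, smoke, >90%) to hard ones (lime, lemon, <60%).

# Normative curve: RANSAC

`fit_ransac_quadratic()` runs the classic hypothesize-and-verify loop:
5,000 iterations, each fitting the quadratic by least squares on 20 random
subjects; inliers are subjects within 6 composite points of the candidate
curve; the candidate with the most inliers wins, ties broken by first
occurrence under the seeded RNG. Two open choices were resolved as follows:

* The reported coefficients are **refit on the consensus inlier set** —
  standard RANSAC practice that stabilizes the curve; the best
  minimal-sample coefficients are retained in `coeffs_minimal` for
  comparison.
* The 6-point band is applied to the **absolute** residual (symmetric),
  and singular minimal samples are skipped and counted.

`deviation_scores()` returns observed − predicted, so negative values mean
odor identification worse than the age norm.

# Voxel-wise GLMs and Monte-Carlo nulls

`fit_voxel_glm()` fits ordinary least squares at every in-mask voxel via a
shared QR decomposition; the t statistic of the predictor of interest is
mapped to a sign-preserving Z through the two-sided t p-value
(`p(T) = p(Z)` to machine precision). Numerically exact fits (zero residual
variance) have no meaningful t; they are reported at a Z cap of ±38 and
flagged. Per-odorant maps (`odorant_maps()`) use the binary identified/not
response as predictor — a covariate-adjusted two-group comparison; odorants
identified by everyone or no one in a sample have no defined map and are
recorded as missing.

**Smoothness estimation.** `estimate_smoothness()` computes the lag-one
spatial autocorrelation of standardized residuals along each axis, pooled
over subjects, inverts it through the Gaussian autocorrelation function
`ρ(Δ) = exp(−Δ²/4σ²)`, and adds the voxel size in quadrature. White noise
therefore reads approximately one voxel, and data smoothed at 6 mm on a
2 mm grid reads ≈ `sqrt(6² + 2²)` mm. Null samplers deconvolve the voxel
size back out, so pure-noise data gets unsmoothed nulls — this
self-consistency is what makes the calibration studies below come out at
the nominal level.

**Cluster-extent correction.** `cluster_correct()` thresholds the map at a
two-sided voxel p (default 0.05), labels suprathreshold clusters
(26-connectivity by default; 6 available), and compares each observed size
to the distribution of the *maximum* cluster size in smoothness-matched
Gaussian null fields (default 10,000 iterations). Null fields are rescaled
to exact unit variance per voxel using the kernel's squared-weight map, so
edge effects do not distort the threshold. The corrected p is floored at
`1/(n_iter + 1)`. Because the null depends only on mask, smoothness,
threshold and connectivity, `cluster_null_distribution()` can be computed
once and shared across maps of the same geometry; a permutation-based
alternative (`permutation_cluster_null()`) provides a cross-method check.

**Odorant-count correction.** `odorant_count_null()` generates 40
independent null maps per iteration (default 5,000 iterations), thresholds
each at two-sided α = 0.05, and records the per-voxel count of significant
maps. The count threshold is the smallest count whose family-wise
probability — via the max-count distribution over the mask — is below 0.05.
On unsmoothed maps the per-voxel count distribution is exactly
Binomial(40, α), which the test suite verifies to total-variation distance
< 0.02.

# PCA odorant biomarkers

`build_assoc_matrix()` assembles the 40 × (tau voxels + amyloid voxels)
matrix of association Z values (the longitudinal variant passes a single
block of follow-up − baseline tau volumes). `pca_components()` centers the
matrix **across odorants** (odorants are the observations; Z values are
already variance-stabilized, so no voxel scaling) and takes the SVD.
Loadings are unit-norm over the 40 odorants; each component is sign-flipped
so its largest-magnitude odorant is positive. Missing odorant rows are
mean-imputed (zero after centering) and flagged. The number of retained
components is either given or chosen as the smallest set reaching a
variance-explained threshold (default 20%) — the selection rule is exposed
because no canonical rule exists for this construction.

One subtlety documented here because it shaped the validation design: the
odorant-centering step removes any common mean from a planted weight
vector, so only the centered part of a ground-truth direction is
recoverable. The rank-one validation generator
(`generate_rank_one_study()`) therefore plants a signed, near-zero-mean
weight gradient (+1…−1 across items, normalized) — like empirical loadings,
which are signed — with a logit-scale effect of 4 (the upper end of the
logistic's near-linear range) so that the planted signal is strongly
detectable: these tests validate the machinery, not the method's
sensitivity limit. At n = 150 subjects and 500 voxels the first component's
loadings recover the planted weights with cosine ≥ 0.9 and subject scores
correlate ≥ 0.8 with the planted severity.

`score_subjects()` is the stated linear combination of binary responses
(optionally centered); with equal weights it reproduces the composite, with
a one-hot weight it reproduces a single item. `backproject()` feeds a score
back through the voxel GLM, optionally adjusting for the other PET
modality's global value and applying cluster correction.

# Along-tract statistics

`skeletonize()` takes a tract mask and two endpoints: the centerline is the
distance-weighted shortest path through the 26-connected voxel graph
(igraph), spline-smoothed and resampled to equal arc-length steps, then cut
into 100 equal-length segments; every mask voxel is assigned to the segment
of its nearest centerline sample (ties toward the lower segment index). Two
implementation decisions matter:

* The path is computed between the endpoints in a **canonical order** and
  mirrored to the requested direction afterwards. Shortest-path tie-breaks
  would otherwise pick different equal-length paths in the two directions;
  with the canonical frame, reversing source and target mirrors the
  skeleton and the profiles *exactly* (`segment k ↔ 101 − k`).
* Segment membership uses `floor`-based arc binning, which is exactly
  symmetric under reversal including points that fall on segment
  boundaries.

`segment_profiles()` averages MD over each segment's voxels per subject;
`along_tract_glm()` fits one GLM per segment (the smell composite as
predictor; age, sex, smoking as default covariates, matching the tract
analysis's covariate set). No multiple-comparison correction is applied
across the 100 segments by default — results are read as a significance
profile along the tract — with an optional Benjamini–Hochberg flag.

The tube phantom (`tract_phantom_spec()`) plants an MD–composite effect of
2×10⁻⁶ mm²/s per UPSIT point (baseline MD 7×10⁻⁴, voxel noise SD 4×10⁻⁵)
on segments 40–60 of a gently curved ~100 mm tube of radius 3 mm on a 2 mm
grid. At n = 82 subjects these values put the planted per-segment t
statistics around 5, so the argmax of |t| falls in segments 35–65 in ≥ 90%
of simulations while null phantoms keep a ~5% per-segment false-positive
rate.

# The directional spreading graph

For source i and target j, `tau_connectivity()` computes the partial
correlation of baseline tau(i) with follow-up tau(j) given
{baseline tau(j)} ∪ covariates, via QR residualization (one conditioning
decomposition per target, reused across sources). Conditioning on the
target's own baseline makes the association reflect longitudinal
accumulation rather than cross-sectional covariance; under linearity it is
equivalent to modeling the change score. Degrees of freedom are
n − 2 − |conditioning set|. Edges at p < 0.05 (uncorrected, as in the
source analysis; an FDR flag exists) form the asymmetric adjacency;
`node_degrees()` sums |r| over significant out/in edges. Degenerate targets
(follow-up numerically identical to baseline after conditioning) are
flagged and excluded rather than reported as significant.

The covariate set for spreading analyses includes the inter-scan interval.
This matters quantitatively in the generator's transfer model
(`follow-up = baseline + β·baseline(source)·Δt + noise`): the planted
partial correlation conditioned on Δt is ≈ 0.7 at the default
β = 0.15/year, baseline SD 0.15, noise SD 0.05 SUVr, whereas leaving the
interval out dilutes it to ≈ 0.4 because the β·mean(baseline)·Δt term acts
as extra noise. Extra baseline-side nodes (e.g. dorsal raphe nucleus mean
diffusivity, which has no longitudinal PET value) enter as sources only.

`pc_skeleton()` implements the classic skeleton phase: starting from the
complete graph, for conditioning-set sizes ℓ = 0, 1, … each remaining edge
X–Y is tested against every size-ℓ subset of the current neighbors of X and
of Y (lexicographic enumeration over sorted neighbor lists, so the output
is deterministic); independence is the Fisher-z test of the partial
correlation (computed from the inverse of the correlation submatrix); the
first independence found removes the edge and records the separating set.
Samples too small for the Fisher-z variance term are refused with the
limiting ℓ reported. `orient_backbone()` then draws an arrow i→j on a
skeleton edge when the bipartite graph has i→j significant but not j→i,
bidirectional when both, undirected when neither. Full PC orientation
(v-structures, Meek rules) is deliberately out of scope: direction comes
from the longitudinal bipartite graph, not from the cross-sectional CPDAG.

# Gene co-expression

`map_samples_to_regions()` follows the stated processing order: per-donor
region means, cross-donor medians, then per-gene z-scoring across regions
(the pipeline is idempotent on already-z-scored input). Samples may carry
explicit region assignments or coordinates (nearest labelled voxel within
4 mm). `coexpression()` is pairwise-complete Pearson correlation across
regions. `cluster_genes()` uses agglomerative clustering on distance
`1 − r` with **average linkage** (the co-expression convention; complete
and Ward are exposed) and picks k by maximum mean silhouette width
(`cluster::silhouette`). `cluster_maps()` averages expression over each
cluster's genes and z-scores the map separately within each hemisphere (the
display convention). `gene_trait_network()` filters associations to the
catalog bound p < 1×10⁻⁵, weights gene–trait edges by the best (minimum)
p-value, and reduces to gene–domain edges (tau, amyloid, Alzheimer's
disease, aging, cognition, brain) again by minimum.

The expression generator plants k latent region profiles and mixes each
gene's profile with noise so that within-cluster pairwise correlation
equals the stated value (default 0.8, the regime in which silhouette
selection recovers k = 4 from 200 genes in ≥ 90% of seeds); an optional
per-cluster right-hemisphere bias supports the hemisphere-asymmetry
checks.

# Orchestration and reproducibility

`run_all()` executes simulate → norms → voxelwise → biomarker → tracts →
graph → genes from one `run_config()`, communicating through files in the
run directory (tables as CSV, volumes and masks as NIfTI-1). Every stage
gets a deterministic sub-seed derived from the master seed; the manifest
(JSON) records package version, stage seeds, outputs and md5 hashes of all
text outputs, so identical configs produce identical manifests. A stage
failure is recorded in the manifest, later stages are marked skipped, and
earlier outputs are retained. Full-study defaults mirror the design's
printed parameters (RANSAC 5000/20/6; count null 5000 × 40; cluster null
10,000); `demo = TRUE` shrinks cohort sizes and iteration counts for a
minutes-scale smoke run.

# Problem sizes used in validation

The shipped validation suite runs entirely on synthetic data at desk
scale, chosen to match the study's sample sizes where those are the
relevant condition: n = 418-scale cohorts for the normative curve (400 in
the recovery study), n = 60 imaging subjects on a 20³ voxel grid for the
Monte-Carlo calibration studies (200 simulated datasets, nulls at 1,000
iterations shared across datasets — the null depends only on geometry,
smoothness and threshold), n = 150/500 voxels for biomarker recovery,
n = 82 for along-tract power (100 simulations), n = 89 for spreading-graph
recovery (100 simulations), 50 seeds for PC-chain and expression-cluster
recovery. The binomial oracle for the count null uses the full 5,000
iterations on a 1,000-voxel mask.

# What passing tests do and do not show

The generators emulate the *statistical* structure the methods consume:
quadratic age trends with gross outliers, regional SUVr with a linear
transfer model, tube-shaped tracts with segment-localized effects,
block-correlated expression. They do not simulate PET physics, scanner
noise spectra, off-target binding, tractography errors, partial-volume
effects, or realistic anatomy — so green tests certify that each method
recovers what it is designed to recover under its own assumptions at
realistic sizes and noise levels, not that those assumptions hold in any
particular cohort. Known limitations worth restating: the odorant-count
null assumes independent maps and is anti-conservative when items are
strongly correlated beyond the modeled covariates; the cluster null's
Gaussian-field surrogate is one common choice among several; and the
spreading graph's edges are uncorrected for the number of region pairs, as
in the source design.
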