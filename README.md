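# olfatau

Olfactory dysfunction, tau accumulation, and tau spreading in the aging
brain — an R implementation of the full analysis pipeline, exercisable end
to end on synthetic data with known ground truth.

Odor identification deficits appear years before cognitive symptoms in
aging and Alzheimer's disease, and the olfactory cortex (anterior olfactory
nucleus, olfactory tubercle, piriform cortex) sits one synapse away from
the medial temporal structures where tau pathology first accumulates. This
package implements the statistical machinery for asking, with baseline
smell testing and two-visit tau-PET: *where* does tau relate to odor
identification, *which combinations* of odorants best predict tau
accumulation, and *in which direction* does tau spread between medial
temporal and olfactory regions?

## What is implemented

| Stage | Core idea |
|---|---|
| `fit_ransac_quadratic()` | Normative aging curve: RANSAC quadratic fit of the 40-item smell composite vs age (5000 iterations, 20-subject samples, 6-point inlier band), per-subject deviation scores |
| `fit_voxel_glm()`, `cluster_correct()`, `odorant_count_null()`, `count_map()` | Voxel-wise GLMs with two Monte-Carlo corrections: a cluster-extent null from smoothness-matched Gaussian fields, and an odorant-count null for "how many of 40 odorant tests hit this voxel by chance" |
| `build_assoc_matrix()`, `pca_components()`, `score_subjects()`, `backproject()` | PCA over the bipartite 40-odorant × voxel Z matrix: odorant-weight biomarkers, subject dysfunction scores, corrected back-projection maps |
| `skeletonize()`, `segment_profiles()`, `along_tract_glm()` | Along-tract statistics: tract mask → centerline → 100 equal-length segments → per-segment MD GLM vs the smell composite |
| `tau_connectivity()`, `node_degrees()` | Directional spreading graph: partial correlation of baseline tau (source) with follow-up tau (target) given the target's own baseline + covariates — an asymmetric region × region matrix |
| `pc_skeleton()`, `orient_backbone()` | PC-algorithm skeleton (Fisher-z conditional independence, growing conditioning sets) pruning indirect connections; arrows from the bipartite graph |
| `map_samples_to_regions()`, `coexpression()`, `cluster_genes()`, `cluster_maps()`, `gene_trait_network()` | Gene co-expression: donor medians + z-scoring, Pearson co-expression, average-linkage clustering with silhouette-selected k, hemisphere-z-scored cluster maps, gene–trait networks weighted by best GWAS p |
| `generate_cohort()`, `generate_regional_tau()`, `paint_volumes()`, `generate_tract_md()`, `generate_expression()`, `generate_rank_one_study()` | Synthetic-data generators that plant known ground truth for every stage |
| `run_config()`, `run_all()` | One-config orchestration of the full synthetic study with seeded stages and a JSON manifest |

The key statistic of the spreading graph: for regions *i → j*,

```
r_ij = pcor( tau_i(baseline),  tau_j(follow-up)  |  tau_j(baseline), age, sex, APOEε4, smoking, Δt )
```

so an edge means baseline tau at the source explains follow-up tau at the
target *beyond* the target's own baseline — longitudinal spreading, not
cross-sectional covariance.

## Worked example

```r
library(olfatau)

co <- generate_cohort(cohort_spec(n_subjects = 418, seed = 42))
fit <- fit_ransac_quadratic(co$age, co$upsit, seed = 43)
fit
#> <ransac_fit> score = 13.72 + 0.8478 * age + -0.00819 * age^2; 396 inliers (threshold 6 points)
```

The fitted curve peaks in the mid-fifties and declines past the seventh
decade; 396 of 418 subjects sit within the 6-point band, and the 22
excluded subjects are the generator's planted low performers:

```r
sort(deviation_scores(fit, co$age, co$upsit))[1:3]
#> -20.3 -19.5 -19.2          # far below their age norm
range(odorant_rates(co))
#> 0.608 ... 0.962            # hard (lime-like) to easy (onion-like) odorants
```

Two-visit regional tau with three planted medial-temporal → olfactory
transfer edges, analyzed by the directional graph:

```r
tr  <- spread_truth()        # Amyg→PirF, Ent→AON, Parahipp→TUR
pan <- generate_regional_tau(co[1:89, ], tr, seed = 44)
g   <- tau_connectivity(pan, covariates = co[1:89, c("age","sex","apoe4","smoking","interval")])
g
#> <spread_graph> 4 directed edges among 8 sources / 8 targets (alpha = 0.05)
head(node_degrees(g)[order(-node_degrees(g)$out_degree), ], 4)
#>     region out_degree in_degree
#>        Ent  0.803      0.000
#>       Amyg  0.721      0.000
#>   Parahipp  0.687      0.000
#>        TUR  0.277      0.687
```

The three planted sources (entorhinal, amygdala, parahippocampus) carry the
largest out-degrees with zero in-degree — tau flows *from* the medial
temporal lobe *toward* the olfactory system in this simulation, and the
analysis recovers that direction. (One extra edge at α = 0.05 over 56
ordered pairs is the expected false-positive count.) The PC backbone on
baseline values correctly prunes everything here because the generator
draws baselines independently; in data with cross-sectional structure it
retains the direct connections, and `orient_backbone(sk, g)` adds the
arrows.

The full synthetic study — cohort, volumes, tracts, graph, genes — runs
from one config:

```r
man <- run_all(run_config("runs/demo", seed = 1, demo = TRUE))
# stage outputs + manifest.json under runs/demo/
```

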