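---
title: "Mapping and explaining the spatial distribution of gliomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and explaining the spatial distribution of gliomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gliotopo)
```

# The scientific question

Gliomas are not scattered uniformly across the brain: they are common in
insular and frontal association cortex and rare in occipital cortex. Three
classes of explanation have been proposed. A *connectomic* account holds
that functional hub regions — nodes carrying many or topologically central
connections — are metabolically costly and therefore vulnerable to
oncogenesis. A *cellular* account points to the putative cells of origin:
neural stem cells, confined to the subventricular zone (adjacent to the
caudate) and the hippocampal dentate gyrus, and oligodendrocyte precursor
cells (OPCs), whose regional density can be estimated from the expression
of OPC marker genes. A *genetic* account expects tumours to arise where
glioma driver genes are normatively transcribed. `gliotopo` implements a
complete analysis pipeline that quantifies all three accounts against a
cohort-level tumour frequency map and integrates them in one regression.

The pipeline's stages are:

1. **Lesion-frequency mapping** (`build_frequency_map`, `smooth_map`,
   `mirror_map`, `parcel_aggregate`): binary tumour masks are averaged into
   a voxel-wise percentage map, smoothed with a 2 mm FWHM Gaussian,
   mirrored to the left hemisphere (homotopic averaging preserves the
   percentage interpretation), and averaged within the parcels of a
   bilaterally symmetric 334-region parcellation (167 per hemisphere, 8 of
   them subcortical per hemisphere), each parcel extended 4 mm into
   unlabelled white matter. Split-half replicability
   (`split_half_replicability`) rebuilds the map from disjoint half-cohorts
   with deliberately unbalanced low-grade fractions (1.5x and 0.5x the
   cohort's ~23%) and reports the inter-parcel Pearson correlation with a
   percentile interval over 100 resplits.
2. **Spatial inference** (`build_spin_ensemble`, `spin_correlation_test`,
   `morans_i`): parcel maps are spatially autocorrelated, so map-map
   correspondence is tested against spatially contiguous "spin" nulls —
   random 3D rotations of the cortical parcels' spherical embedding — not
   against value shuffles.
3. **Hub profiling** (`build_parcel_connectome`, `hub_metrics`,
   `homotopic_average`, `screen_redundant_metrics`,
   `hub_frequency_association`): a weighted functional connectome is built
   by correlating per-parcel component loadings (negatives and the
   diagonal zeroed), seven hub metrics are computed per node, homotopic
   pairs are averaged, metrics with |Spearman| > 0.95 against nodal
   strength are screened out, and the survivors are spin-tested against
   tumour frequency.
4. **Cells of origin** (`nsc_niche_test`, `coexpression_specificity`,
   `filter_gene_set`, `marker_score_map`): tumour frequency at the two
   neural-stem-cell niche parcels (hippocampus and caudate stand-ins) is
   compared with random parcel pairs; the OPC marker set is checked for
   spatial co-expression against random same-size gene sets, filtered of
   discordant members, and its median regional enrichment is spin-tested
   against tumour frequency.
5. **Transcriptomics** (`align_samples_to_frequency`, `fit_pls`,
   `permute_pls_significance`, `bootstrap_gene_z`, `rank_enrichment_test`,
   `map_loadings_to_parcels`): expression samples are aligned to the
   (separately smoothed and mirrored) frequency map, the square-rooted
   frequency is regressed on z-scored expression by partial least squares,
   model significance comes from shuffling the sample labels, per-gene
   bootstrap z-statistics rank all genes, and a driver gene set is tested
   for median-rank enrichment. Ranked lists are exported whole — no
   significance cut — for external ontology tools.
6. **Integration** (`assemble_design`, `fit_glioma_model`,
   `partial_variance`, `predictor_spin_pvalues`): z-scored sqrt tumour
   frequency is regressed on z-scored nodal strength, OPC score, and
   PLS1/PLS2 parcel loadings; an interaction model gates the main-effects
   model; each predictor's squared partial correlation is tested against
   nulls in which the response map is spun.

# The synthetic study

Real inputs of this design — a tumour-segmentation cohort, a
population-average dense connectome, a donor expression atlas — are large
external datasets. The `fixtures` module generates synthetic inputs with
the statistical structure the analysis relies on, so the whole pipeline is
testable and reproducible offline. `run_pipeline(synthetic_config())`
executes the entire study.

**What the generator emulates.** A mirror-symmetric parcellation carved
from a voxel grid (167 parcels per hemisphere, 8 subcortical, contiguous
by construction, with designated hippocampus/caudate stand-ins); spatially
autocorrelated ground-truth fields (Gaussian-process draws on parcel
centroids, squared-exponential kernel, default length-scale 12 mm);
a lesion cohort of 335 patients (~23% low grade) whose spherical lesions
are placed with parcel probabilities proportional to the tumour truth
field; per-parcel connectome loadings (1200 components) whose correlations
realize a 7-community modular graph in which nodal strength tracks a hub
truth field; and a samples-by-genes expression atlas (600 left-hemisphere
samples, 2000 genes by default) with planted marker and driver gene sets
and decoy members.

**Exact effect-size planting.** Every planted correlation (field pairs,
marker/driver profiles vs. the target map, background latent factors vs.
the target) is exact in sample: the nuisance component is orthogonalized
against the base signal before mixing. Smooth spatial fields have few
effective degrees of freedom, so without orthogonalization a nominal 0.5
correlation realized anywhere between 0.0 and 0.7 across seeds, and
"planted effect" would not have been a meaningful experimental condition.
The tumour-hub and tumour-cell field correlations, and the marker/driver
profile correlations, default to 0.5 ("moderate" effects; the power
properties of the pipeline are stated at this value). The pipeline hands
the *measured* parcel tumour-frequency map (sqrt scale) to the expression
generator as the target, so gene-level effects refer to the map the PLS
actually regresses on, as in the real study design.

**What the generator does not emulate.** Tumour growth and infiltration
dynamics (lesions are log-normal spheres; only placement frequency matters
downstream); fMRI time-series structure (loadings are Gaussian factors);
donor/probe structure of expression atlases; and — importantly — the
sheet-like geometry of real cortex: the synthetic "cortex" is a solid
block. Consequences of the last point are handled explicitly below.
Passing tests therefore demonstrate the correctness and calibration of the
*procedures* under these controlled conditions, not properties of any
real cohort.

# Geometry, the spin test, and Moran's I

The spin test requires a spherical embedding of cortical parcels. Real
analyses obtain one from surface registration; synthetic parcels need one
by construction. Raw radial projection of carved-box parcels is too
non-uniform for a rotation to be matched back onto the original
configuration, so projected centroids are snapped one-to-one onto a
per-hemisphere Fibonacci lattice, preserving neighbourhood relations while
making the configuration near rotation-invariant.

Rotated centroids are matched to originals by a greedy nearest-first
assignment refined with 2-opt swaps. The default matching is *bijective*,
so every spun map is an exact permutation of the original values —
value-multiset conservation holds, and duplicated-donor artefacts (which
measurably inflate the autocorrelation of spun maps) are avoided. The
non-bijective nearest-centroid variant remains available
(`bijective = FALSE`). Subcortical parcels have no surface embedding and
are permuted uniformly among themselves (or excluded).

Because the synthetic cortex is volumetric, two geometries coexist:
`morans_i(metric = "volume")` measures autocorrelation between volumetric
centroids, while `metric = "sphere"` measures it on the spherical
embedding — the geometry the spin null preserves, and the right diagnostic
for spin-null fidelity (on these fixtures spun maps retain about 90% of
the original sphere-metric Moran's I, while value shuffles collapse to the
permutation-null expectation of -1/(n-1)). Calibration simulations
generate fields smooth in the sphere geometry
(`make_parcel_field(geometry = "sphere")`): a field smooth only in the
solid volume carries radial structure that no rotation of the surface can
reproduce, and no spin test — here or on real data — is exchangeable for
such structure.

**P-value conventions.** All resampling p-values use the +1-corrected
estimator, so the floor is 1/(n+1) and no p is ever exactly zero.
One-sided spin tests take a *prespecified* direction (default: positive,
matching the directional hub/OPC/driver hypotheses); choosing the
direction from the observed sign (`direction = "auto"`) is supported for
exploration but documented as anti-conservative by up to a factor of two.
Empirically, the spin test's size at nominal 0.05 is about 0.06 on these
fixtures — parcel-level spin nulls are slightly under-dispersed because
matched rotations are not perfect isometries; this is a known property of
the method family, and the calibration suite asserts the spec'd band.

# Parameters that matter

| Parameter | Default | Units | Where |
|---|---|---|---|
| smoothing FWHM | 2 | mm | `smooth_map`, sample alignment |
| white-matter extension | 4 | mm | `parcel_aggregate` (ties: nearest labelled voxel, then lower parcel id) |
| redundancy screen | 0.95 | Spearman rho | `screen_redundant_metrics` (stability reported over 0.65-0.99) |
| spins / parcel pairs | 10 000 | draws | spin ensembles, `nsc_niche_test` |
| permutations / bootstraps | 1000 | draws | `permute_pls_significance`, `bootstrap_gene_z` |
| co-expression null sets | 1000 | draws | `coexpression_specificity` (10 000 variant one argument away) |
| split-half repeats | 100 | resplits | `split_half_replicability` (95% percentile interval) |
| edge lengths | 1/weight | — | shortest-path metrics |
| PLS components | 2 | — | `fit_pls` (scree of further components reported) |
| multiple-comparison correction | Bonferroni x4 | — | `predictor_spin_pvalues` (fdr/none available) |

# Numerical and design choices

- **Mirroring** averages homotopic voxels rather than summing or
  max-pooling, preserving the percentage scale; the unsmoothed, unmirrored
  map is kept because the expression alignment smooths and mirrors it
  independently.
- **Smoothing kernels** are renormalized at grid edges so constant maps
  are preserved exactly; sigma = FWHM / (2 sqrt(2 ln 2)) per axis.
- **PLS** is single-response NIPALS with X-deflation: unit-norm weight
  vectors, orthogonal scores, and per-component response-variance
  *increments* (the deflated definition; reported as such). Bootstrap
  components are sign-aligned to the original fit by weight-vector dot
  product before z-statistics are formed; collapsed draws are redrawn and
  counted. Gene ties rank deterministically by identifier.
- **Gene-set filtering** is a single pass removing genes whose mean
  correlation with the rest of the set is non-positive, matching a
  single-step filter design; it is empirically idempotent on these
  fixtures but not by construction.
- **Niche null pairs** are sampled with replacement across draws, distinct
  within a pair, and may include the niche parcels themselves; an
  exhaustive all-pairs mode exists for exact toy-scale verification, and
  the same option exists for median-rank enrichment.
- **Zero-filling** in the integrative design happens after z-scoring, so
  filled cells sit at the column mean; filled cells are flagged in
  metadata. The interaction-model gate uses per-term p < 0.05,
  uncorrected, and is reported transparently.
- **Reported "PLS loadings" for visualization** are per-sample component
  scores; parcels take the median over their nearest-assigned samples,
  and empty parcels take the group mean score.
- **Determinism**: every generator consumes sub-seeds derived from the one
  configured seed; identical configurations give bit-identical outputs,
  and the run manifest records a content hash that re-runs must reproduce.

# Problem sizes used by the test and acceptance suites

The shipped suites run the full-scale parcellation (334 parcels) for
geometry-sensitive properties and reduced cohorts/atlases elsewhere:
calibration uses 500 simulated map pairs with 1000 spins each; power uses
100 map pairs at effect 0.5 and 50 expression cohorts with 30 planted
drivers among 2000 genes (bootstrap of 100 for rank stability); parameter
recovery uses 100 designs of 167 parcels; graph oracles enumerate all
simple paths on graphs of up to 12 nodes. The default end-to-end run
(`run_pipeline` with `pipeline_params()`) uses the full 10 000-spin /
1000-bootstrap settings. These sizes are the package's chosen study
conditions and are what the reported properties refer to.

# Known limitations

- The spin null's empirical size (~0.06 at nominal 0.05) is slightly
  anti-conservative; consumers needing strict control should use the
  two-sided option or larger alpha margins.
- Sphere-geometry calibration statements do not extend to maps whose
  autocorrelation is predominantly radial/volumetric.
- The split-half confidence interval is a percentile interval over
  resplits of one cohort; it quantifies assignment noise, not sampling of
  new cohorts.
- Subcortical parcels are uniformly permuted in spin nulls; with only 8
  per hemisphere their contribution to null variance is coarse.
- The synthetic NSC niche carries no planted frequency elevation, so the
  niche test on synthetic runs is a calibration exercise (its p-value is
  approximately uniform), not a power demonstration.
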