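# bundleatlas

Probabilistic multi-scale white-matter bundle atlases from diffusion-MRI
tractography — construction, a compact HDF5 file format, and
tractography-free application to new imaging data.

## The problem

Structural connectomics normally requires diffusion-weighted MRI,
tractography and careful bundle dissection for every subject. Many
datasets — clinical lesion studies, quantitative T1/T2 mapping, older
cohorts — have no usable diffusion data, yet their scalar maps could
still be analyzed *connection-wise* if one knew where each white-matter
bundle runs. A probabilistic bundle atlas solves this: bundles are
dissected once in a healthy cohort, summarized as voxel-wise probability
maps in a standard space, and then applied to any co-registered volume.

`bundleatlas` implements that whole workflow for R users:

1. **Dissection** — a whole-brain tractogram plus a labeled gray-matter
   parcellation is cut into region-pair bundles `C_{k,i,j}` (scale `k`,
   regions `i < j`). Streamlines are kept if their geodesic length lies
   in [20, 200] mm, assigned by their endpoint voxels, then cleaned:
   loops (total winding > 360°) are removed, and spatial outliers are
   rejected with a QuickBundles cluster tree (MDF metric, tree-score
   threshold 0.2). Per-subject NOS (number-of-streamlines) and
   mean-length matrices come out alongside.
2. **Atlas construction** — per bundle and subject, a tract density
   image (TDI) counts streamlines per voxel (exact geometric
   traversal). Binarizing TDIs, summing across the `S` subjects and
   dividing by `S` yields the bundle's spatial probabilistic anatomical
   map (SPAM): `P(v) = count(v) / S` is the probability that voxel `v`
   is traversed. Group matrices (consistency, mean NOS, mean length)
   are computed, and the atlas bundle list is fixed by
   distance-dependent **consensus thresholding**: per hemisphere class
   (intra/inter) and per length bin, keep the most consistent
   candidates until the group network matches the average subject
   density, preserving the length distribution.
3. **Serialization** — one HDF5 file per scale with groups `header/`
   (grid + region metadata), `matrices/` (`consistency`,
   `numbStlines`, `length`) and `atlas/` (one `N×4` dataset per bundle,
   named `i_j`, holding voxel x, y, z and the per-voxel subject count).
4. **Application** — given any scalar volume on the atlas grid:
   mean/median/std connectivity matrices over each bundle's thresholded
   support (voxel-wise probability threshold `p_thr`, inter-subject
   consistency threshold `c_thr`, both defaulting to 0.3); ROI bundle
   queries; union masks; and lesion "dysconnectome" reports with
   probability-weighted lesion loads. Test–retest utilities implement
   `perCh = (X₂ − X₁)/X₁ × 100`, Bland–Altman limits of agreement,
   Lin's concordance correlation with CI, and Pearson + FDR.
5. **Phantom** — a seeded generator of hemisphere-structured block
   parcellations, multi-subject tractograms with known ground truth,
   scalar maps with injected per-bundle values, and spherical lesions,
   so every stage is testable end to end without any imaging data.

## Worked example

```r
library(bundleatlas)

spec <- phantom_spec(seed = 42)            # 48^3 grid, 2 regions/hemisphere
res  <- build_phantom_atlas(spec, nsubjects = 20)
res$atlas
#> atlas_model: 4 regions, 2 bundles, 20 subjects
atlas_density_summary(res$atlas)
#>   scale n_regions n_bundles  density
#> 1     1         4         2 33.33333

# scalar-weighted connectome from one subject's (noiseless) scalar map
sc <- scalar_connectome(res$atlas, res$scalars[[1]],
                        p_thr = 0.5, c_thr = 0.3)
sc$mean[1, 3]   # 0.4  -- exactly the value injected along bundle 1_3
sc$mean[2, 4]   # 0.8  -- exactly the value injected along bundle 2_4

# lesion dysconnectome: a 4 mm sphere on the first bundle's arc
tr  <- res$tractograms[[1]]
arc <- tr$streamlines[[which(tr$edge_index == 1)[1]]]
lesion <- make_lesion_mask(res$parcellation, arc[nrow(arc) %/% 2, ], 4)
lesion_impact(res$atlas, lesion, p_thr = 0.3, c_thr = 0.3)$pairs
#>    i j name_i name_j      load voxel_fraction affected
#> i  1 3     L1     R1 0.2423569      0.2638889     TRUE
#> i1 2 4     L2     R2 0.0000000      0.0000000    FALSE
```

The lesion load is the probability-weighted fraction of the bundle's
thresholded support covered by the lesion, so the sphere on bundle
`1_3` affects only that connection.

A thin command-line wrapper is installed as `exec/bundleatlas`
(subcommands `phantom`, `build-atlas`, `apply`, `query-roi`, `lesion`,
`metrics`, `summary`); it produces byte-identical results to the
library calls.

## Scope

The package consumes parcellations, tractograms, scalar maps and masks;
it does not perform MRI preprocessing, fODF estimation, tractography,
surface parcellation or registration estimation (transforms are applied
to points, not estimated). Inputs to the application functions must
already live on the atlas grid — there is no silent resampling.
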