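---
title: "Methods: probabilistic bundle atlases, consensus thresholding and the phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic bundle atlases, consensus thresholding and the phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `bundleatlas`
implements, the parameters that matter, and the design decisions taken
where the methodology left genuine freedom. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## From tractogram to bundles

A tractogram is a set of streamlines — polylines in world millimeters
(RAS) — with the grid metadata of the space they were reconstructed in.
Dissection (`extract_bundles()`) proceeds in three stages:

1. **Length filter.** Streamlines with geodesic length outside
   [`min_len`, `max_len`] are discarded; the defaults 20 and 200 mm
   (inclusive bounds) are the conventional whole-brain tractography
   filter. Very short streamlines are dominated by noise near the
   gray-white interface; very long ones are usually propagation
   artifacts.
2. **Endpoint assignment.** Each surviving streamline is assigned the
   unordered pair of parcellation labels at the voxels containing its
   first and last point. Lookup is exact-voxel, with no search radius:
   anatomically constrained tractography terminates inside gray matter,
   and the parcellation is expected to be dilated 2 mm into the white
   matter first (`dilate_parcellation()`) exactly to make this true.
   Streamlines ending in background or with both endpoints in the same
   region are left unassigned; self-connections are not counted (the
   matrix diagonal is structurally zero).
3. **Cleaning.** Per bundle, loops — total unsigned winding strictly
   greater than 360 degrees — are removed first. Remaining streamlines
   are clustered with QuickBundles (single pass, minimum average
   direct-flip distance on 12-point resamplings; a streamline joins the
   first cluster whose centroid is nearer than the threshold) at the
   decreasing threshold sequence 10, 5, 2.5 mm. A streamline's outlier
   score is the mean, over the three levels, of its cluster's size
   fraction; scores below 0.2 are rejected. A coherent streamline in a
   bundle of m members scores near 1, a spatially isolated one near
   1/m. The precise cluster-tree construction behind the published 0.2
   cut is not fully specified in the source material; this three-level
   mean is our documented reconstruction, keeping the 0.2 threshold.
   Bundles of two or fewer streamlines skip this stage (a size fraction
   would be meaningless).

NOS and mean-length matrices are computed **after** cleaning, since the
cleaned bundles are what the atlas aggregates.

Winding is the sum of unsigned turning angles, so loops in either
direction count; the threshold is strictly greater than 360°, so a
closed planar convex polyline (exactly 360°) is not a loop.

## Atlas construction

**TDI.** The tract density image counts, per voxel, the streamlines
traversing it. Traversal is computed *exactly*: each segment is
subdivided at its crossings of voxel-boundary planes (half-integer
planes in continuous voxel coordinates) and the polyline is evaluated
at midpoints between consecutive crossings, which identifies precisely
the voxels whose cube the polyline passes through. A fixed-step walk
(e.g. 0.2 × voxel size) systematically misses briefly-grazed voxels —
on oblique 1 mm-grid paths we measured on the order of 10% of voxels
clipped more briefly than one step — so the exact construction is used
instead and is validated in the tests against an independent
segment-cube (slab) intersection oracle.

**SPAM.** Per bundle: binarize each subject's TDI at one streamline,
sum the binary masks over all S subjects, store the voxels with
non-zero count. `count/S` is the probability that a voxel is traversed
in a random cohort member; probabilities are therefore in (0, 1].
The mean TDI divides the raw sum by S, counting absent subjects as
zeros.

**Group matrices.** `consistency` is the number of subjects with at
least one streamline for the pair; `numbStlines` the mean NOS over all
S subjects; `length` the mean of per-subject mean lengths over the
subjects that have the connection (0 where none does).

**Consensus thresholding.** The atlas bundle list is fixed so that the
group network's density matches the average subject's, separately for
intra-hemispheric (both regions L or both R) and inter-hemispheric
connections (midline-involving pairs count as inter-hemispheric), while
preserving the connection-length distribution:

* candidates are pairs with `consistency >= ceil(c_min * S)` — and at
  least one subject: a pair observed in no subject has no defined
  length and no SPAM, so it can never be a candidate even at
  `c_min = 0`;
* within each class, candidates are split into `n_bins` equal-count
  bins of group mean length (default `n_bins = 10`; the bin count is
  not prescribed by the methodology, and equal-count bins keep every
  bin populated);
* each bin's target is the rounded mean, over subjects, of how many of
  that subject's existing connections of the class fall into the bin —
  a connection that is itself a candidate takes its candidate bin
  directly (this makes the procedure exact under tied lengths), others
  are binned by the candidate bins' length boundaries;
* the target most-consistent candidates are kept per bin, ties broken
  by higher consistency, then higher mean NOS, then lexicographic
  region codes. Determinism was preferred over fidelity to an
  unspecified original tie rule.

`c_min` defaults to 0 at build time; the 30% consistency cut is an
application-time recommendation, and both knobs are exposed.

## File format and conventions

Voxel indices are 0-based everywhere (matching the NIfTI convention
that the affine maps index 0 to the first voxel center); the HDF5
reader has an `index_base` argument for files written 1-based, and
region hemispheres — not part of the on-disk layout — are inferred from
the leading L/R of region names on read. Counts are stored as
integers, matrices as doubles (consistency as integers). Bundle
datasets are named `"{min}_{max}"` by region code.

## Applying an atlas

The two free parameters are the voxel-wise probability threshold
`p_thr` and the inter-subject consistency threshold `c_thr`, both
inclusive (`>=`) and both defaulting to 0.3 — the configuration
recommended for scalar-weighted connectomes. `c_thr` is a fraction of
subjects, mapped to `ceil(c_thr * S)` whole subjects (with a 1e-9
slack in the product so floating-point noise cannot shift the integer
cut). Connections failing a cut are flagged invalid, never zeroed: 0
is a legal scalar mean. The standard deviation uses population (divide
by n) normalization. Inputs must already be on the atlas grid; the
package never resamples silently, because registration quality is the
dominant error source in atlas-based analyses and must remain under
the user's control.

Lesion load is defined probability-weighted:
`load = sum(P(v), v in support AND lesion) / sum(P(v), v in support)`;
the published material gives no formula, and weighting by the SPAM
probability makes voxels that are reliably part of the bundle dominate.
The unweighted voxel fraction is reported alongside for transparency.
ROI queries use support-intersection semantics (a bundle "connects"
ROIs if its thresholded support touches at least two distinct labels),
which is the more permissive and geometry-driven reading; endpoint-only
semantics can be recovered by masking with the endpoint regions.

## Agreement statistics

Test–retest percentage change is `(X2 − X1)/X1 × 100` per connection,
defined only where both connectomes are valid and the baseline is
non-zero (guarded, never ±Inf). Bland–Altman uses the sample (n−1)
standard deviation and 1.96 limits. Lin's concordance correlation uses
sample moments, `ccc = 2 cov / (var x + var y + (mean x − mean y)²)`;
its 95% CI is computed on the Fisher z scale with Lin's asymptotic
variance (the published tables report CIs without naming a method; the
Fisher-z construction is the standard choice and is documented as
ours). Pearson correlations across connection sets are corrected with
Benjamini–Hochberg at q = 0.05 by default; constant sets are excluded
from the correction and flagged invalid. Cortical coverage is counted
on a voxel interface mask (per voxel, the number of distinct bundles
whose thresholded support contains it) with optional per-class
histograms — a voxel-based surrogate for surface-vertex counting, since
surface meshes are out of scope.

## The phantom: what it emulates, and what it does not

The generator produces a 48³ voxel, 1 mm grid with 8³-voxel cuboid
"gray-matter" regions — per hemisphere, stacked along y, left blocks at
low x, right at high x, hemisphere assigned by the mid-x plane — and a
white-matter corridor between them. Each ground-truth edge produces,
per subject, `max(1, Poisson(rate))` streamlines with probability
`presence`; a streamline is a quadratic Bezier arc between the two
regions with a 6 mm perpendicular apex offset (curved enough to
exercise winding and exact voxel traversal, far below the 360° loop
threshold) and Gaussian apex jitter of sd `jitter` (default 1 mm).
Arc lengths fall in [20, 200] mm by construction (the apex is doubled
if an arc is short). Loop and outlier streamlines are available as
explicit injectors rather than silent contaminants.

Two deliberate design choices:

* **Endpoints are anchored.** Each edge's streamlines start and end at
  the region's centroid voxel, with sub-voxel jitter capped at 0.45
  voxel. Endpoints therefore always fall inside labeled voxels (the
  exact-voxel endpoint lookup is guaranteed to succeed, as it is for
  anatomically constrained tractography in real data), and with
  `jitter = 0` all subjects produce identical streamlines.
* **The default adjacency is a homotopic left-right matching**, i.e.
  vertex-disjoint edges, and scalar maps paint each edge's value over a
  tube of radius `2 + 3*jitter` mm around the subject's bundle (later
  edges overwrite earlier ones, in edge-list order). Disjoint edges
  keep the painted tracts spatially disjoint, and the tube radius
  covers the inter-subject spread, so the atlas-level thresholded
  support lies inside every subject's painted tract and the injected
  value is recovered *exactly* by `scalar_connectome()`. Edges sharing
  an endpoint region necessarily overlap near it, where overwriting
  makes exact recovery impossible by construction; configurations with
  intra-hemispheric edges are supported (and used to exercise the
  consensus classes) but tested for consistency and retention rather
  than exact scalar recovery.

Per-subject seeds derive from the master seed by
`(master * 1000003 + subject * 7919) mod (2^31 − 1)`; scalar-map noise
uses a further fixed offset. All outputs are bit-reproducible per seed.

What the phantom does **not** emulate: crossing and kissing fibers,
partial-volume effects, registration error, gyral termination bias,
realistic SNR, or anatomical variability beyond Gaussian arc jitter.
Passing the phantom suite therefore demonstrates the correctness of
the bookkeeping, geometry and statistics — not the anatomical validity
of any particular real-data atlas.

## Problem sizes and numerical choices

The test suite and acceptance script run the pipeline at 20 subjects on
the 48³ grid (with 3- and 5-subject variants for I/O and jitter-free
checks), sizes chosen so the whole suite completes in well under a
minute while every consistency count, SPAM probability and retention
decision remains exactly checkable against brute-force oracles.
Degenerate inputs are handled explicitly: zero-length segments are
skipped in winding and resampling; fully-degenerate streamlines
resample to repeated points; MDF of identical or reversed streamlines
is exactly 0; dilation ties break toward the lower region code;
`compress_streamline()` is endpoint-anchored recursive farthest-point
removal, so the result is always a subset of the input points
containing both endpoints and every removed point lies within
`max_error` (default 0.2 mm) of the output polyline — only this error
contract, not any particular published algorithm's internals, is
promised.

## Known limitations

* Tractograms are exchanged via the package's documented TSV container;
  TRK/TCK binary containers are not read (no R-level reader exists in
  the supported dependency set).
* Surface meshes are out of scope: cortical coverage and gyral/sulcal
  splits operate on voxel masks and user-supplied voxel class labels.
* The consensus bin count and the outlier cluster-tree levels are
  documented reconstructions where the published description is silent;
  both are exposed as parameters.
* `read_atlas_h5()` validates shapes and count ranges but cannot detect
  semantically wrong (as opposed to malformed) files.
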