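#' Synthetic connectome phantom
#'
#' A seeded generator producing hemisphere-structured block parcellations,
#' multi-subject tractograms with known ground-truth adjacency, scalar
#' maps with known per-bundle values, and spherical lesion masks -- so
#' every pipeline stage is testable without imaging data.
#'
#' The default ground truth is a homotopic left-right matching: each left
#' region connects to its right counterpart through a curved (quadratic
#' Bezier) arc. Matching edges are vertex-disjoint, so the painted scalar
#' tracts are spatially disjoint and injected per-edge values are exactly
#' recoverable from atlas-based sampling. Custom edge lists (e.g. with
#' intra-hemispheric edges) can be supplied.
#'
#' @name phantom
NULL

.phantom_palette <- matrix(c(
  255, 0, 0,    0, 200, 0,    0, 0, 255,    255, 200, 0,
  200, 0, 200,  0, 200, 200,  255, 120, 0,  120, 80, 40
), ncol = 3L, byrow = TRUE)

#' Phantom specification
#'
#' @param grid_dim grid dimensions (default 48^3).
#' @param voxsize voxel sizes in mm (default 1 mm isotropic).
#' @param n_regions regions per hemisphere (>= 1, default 2).
#' @param edges two-column matrix of ground-truth region-code pairs;
#'   default: the homotopic matching `cbind(1:n, n + 1:n)`.
#' @param presence per-edge subject-presence probability in `[0, 1]`
#'   (recycled; default 1).
#' @param rate per-edge Poisson streamline rate (min one streamline when
#'   the edge is present; recycled; default 5).
#' @param jitter spatial jitter sd in mm applied to the arc apex
#'   (default 1).
#' @param scalar_values per-edge injected scalar value; default equally
#'   spaced in `[0.4, 0.8]`.
#' @param background background scalar value (default 0.2).
#' @param noise_sd additive Gaussian noise sd on scalar maps (default 0).
#' @param apex perpendicular apex offset of the arcs in mm (default 6);
#'   keeps bundles curved but winding well below 360 degrees.
#' @param paint_radius radius (mm) of the scalar tract painted around a
#'   subject's bundle; default `2 + 3 * jitter`, wide enough that the
#'   group-level bundle support lies inside every subject's painted
#'   tract.
#' @param seed master seed; per-subject seeds are derived by a fixed
#'   splitting rule (see [phantom_subject_seed()]).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(48L, 48L, 48L), voxsize = c(1, 1, 1),
                         n_regions = 2L, edges = NULL, presence = 1,
                         rate = 5, jitter = 1, scalar_values = NULL,
                         background = 0.2, noise_sd = 0, apex = 6,
                         paint_radius = NULL, seed = 42L) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("n_regions must be >= 1 per hemisphere")
  if (is.null(edges))
    edges <- cbind(seq_len(n_regions), n_regions + seq_len(n_regions))
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  ne <- nrow(edges)
  presence <- rep_len(presence, ne)
  rate <- rep_len(rate, ne)
  if (any(presence < 0 | presence > 1)) stop("presence must be in [0, 1]")
  if (any(rate < 0)) stop("rate must be >= 0")
  if (jitter < 0) stop("jitter must be >= 0")
  if (is.null(scalar_values))
    scalar_values <- if (ne == 1L) 0.6 else
      seq(0.4, 0.8, length.out = ne)
  scalar_values <- rep_len(scalar_values, ne)
  if (is.null(paint_radius)) paint_radius <- 2 + 3 * jitter
  structure(list(grid_dim = as.integer(grid_dim),
                 voxsize = as.numeric(voxsize),
                 n_regions = n_regions, edges = edges,
                 presence = presence, rate = rate, jitter = jitter,
                 scalar_values = scalar_values, background = background,
                 noise_sd = noise_sd, apex = apex,
                 paint_radius = paint_radius, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Per-subject seed splitting rule
#'
#' `(master * 1000003 + subject * 7919) mod (2^31 - 1)`, keeping derived
#' seeds within R's integer range.
#'
#' @param master master seed.
#' @param subject 1-based subject index.
#' @return integer seed.
#' @export
phantom_subject_seed <- function(master, subject) {
  as.integer((as.double(master) * 1000003 + as.double(subject) * 7919) %%
               2147483647)
}

#' Build the phantom parcellation
#'
#' Non-overlapping cuboid regions: left-hemisphere blocks at low x, right
#' at high x (hemisphere L iff the voxel center is left of the mid-x
#' plane), stacked along y with a white-matter corridor between them.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_volume()]; unlabeled voxels form the WM corridor
#'   (see [phantom_wm_mask()]).
#' @export
make_phantom_parcellation <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_dim
  vs <- spec$voxsize
  affine <- diag(c(vs, 1))
  n <- spec$n_regions
  bs <- 8L  # block edge, voxels
  slot <- (dm[2L] - 4L) %/% n
  if (slot < bs || dm[1L] < 2L * (bs + 4L) || dm[3L] < bs + 4L)
    stop("regions don't fit the grid: enlarge grid_dim or reduce ",
         "n_regions")
  labels <- array(0L, dm)
  xl <- 2L + seq_len(bs)          # 1-based array ranges
  xr <- dm[1L] - 2L - bs + seq_len(bs)
  z0 <- (dm[3L] - bs) %/% 2L
  zr <- z0 + seq_len(bs)
  tab <- list()
  for (b in seq_len(n)) {
    y0 <- 2L + (b - 1L) * slot + (slot - bs) %/% 2L
    yr <- y0 + seq_len(bs)
    for (side in 1:2) {
      code <- if (side == 1L) b else n + b
      xrange <- if (side == 1L) xl else xr
      labels[xrange, yr, zr] <- code
      # centroid of voxel centers, in mm (0-based indices times voxsize)
      cen <- c(mean(xrange - 1L) * vs[1L], mean(yr - 1L) * vs[2L],
               mean(zr - 1L) * vs[3L])
      col <- .phantom_palette[(b - 1L) %% nrow(.phantom_palette) + 1L, ]
      tab[[length(tab) + 1L]] <- data.frame(
        code = code,
        name = paste0(if (side == 1L) "L" else "R", b),
        hemisphere = if (side == 1L) "L" else "R",
        R = col[1L], G = col[2L], B = col[3L],
        x = cen[1L], y = cen[2L], z = cen[3L],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, tab)
  tab <- tab[order(tab$code), ]
  rownames(tab) <- NULL
  label_volume(labels, affine, tab)
}

#' White-matter mask of a phantom parcellation
#'
#' @param p the phantom [label_volume()].
#' @return logical array: the unlabeled corridor.
#' @export
phantom_wm_mask <- function(p) {
  p$labels == 0L
}

# integer anchor voxel (0-based) of a region: the labeled voxel nearest
# the region centroid (lowest linear index on ties)
.region_anchor <- function(p, code) {
  idx <- which(p$labels == code, arr.ind = TRUE) - 1L
  cen <- unlist(p$table[match(code, p$table$code), c("x", "y", "z")])
  w <- .voxel_to_world(p$affine, idx)
  d <- rowSums(sweep(w, 2L, cen)^2)
  idx[which.min(d), ]
}

# quadratic Bezier through p0, apex-controlled p1, p2
.bezier <- function(p0, p1, p2, m = 40L) {
  tt <- seq(0, 1, length.out = m)
  b0 <- (1 - tt)^2
  b1 <- 2 * tt * (1 - tt)
  b2 <- tt^2
  outer(b0, p0) + outer(b1, p1) + outer(b2, p2)
}

.perp_unit <- function(chord) {
  u <- c(chord[2L] * 1 - chord[3L] * 0, chord[3L] * 0 - chord[1L] * 1,
         chord[1L] * 0 - chord[2L] * 0)  # chord x (0,0,1)
  if (sum(u^2) < 1e-9)
    u <- c(-chord[3L], 0, chord[1L])     # chord x (0,1,0)
  u / sqrt(sum(u^2))
}

#' Simulate one subject's tractogram
#'
#' For each ground-truth edge: present with its presence probability; if
#' present, `max(1, Poisson(rate))` streamlines, each a quadratic arc
#' between the two region anchor voxels with sub-voxel endpoint jitter
#' (capped at 0.45 voxel so endpoints stay inside the labeled voxels) and
#' Gaussian apex jitter of sd `jitter` mm. Arc lengths lie within
#' \[20, 200\] mm by construction (the apex is doubled if an arc falls
#' short). With `jitter = 0` every subject produces identical
#' streamlines.
#'
#' @param phantom the phantom [label_volume()].
#' @param spec the [phantom_spec()].
#' @param subject 1-based subject index (determines the derived seed).
#' @return a [tractogram()] with an extra `edge_index` integer vector
#'   giving the ground-truth edge of each streamline.
#' @export
simulate_subject_tractogram <- function(phantom, spec, subject) {
  stopifnot(inherits(phantom, "label_volume"),
            inherits(spec, "phantom_spec"))
  set.seed(phantom_subject_seed(spec$seed, subject))
  vs <- spec$voxsize
  sub_jit <- if (spec$jitter > 0) 0.45 else 0
  anchors <- lapply(seq_len(nrow(phantom$table)), function(k)
    .region_anchor(phantom, phantom$table$code[k]))
  names(anchors) <- phantom$table$code
  sls <- list()
  edge_index <- integer()
  for (e in seq_len(nrow(spec$edges))) {
    if (stats::runif(1L) > spec$presence[e]) next
    if (spec$presence[e] == 0) next
    k <- max(1L, stats::rpois(1L, spec$rate[e]))
    a0 <- .voxel_to_world(phantom$affine,
                          rbind(anchors[[as.character(spec$edges[e, 1L])]]))
    a2 <- .voxel_to_world(phantom$affine,
                          rbind(anchors[[as.character(spec$edges[e, 2L])]]))
    for (s in seq_len(k)) {
      p0 <- as.numeric(a0) + stats::runif(3L, -sub_jit, sub_jit) * vs
      p2 <- as.numeric(a2) + stats::runif(3L, -sub_jit, sub_jit) * vs
      chord <- p2 - p0
      u <- .perp_unit(chord)
      apex_jit <- stats::rnorm(3L, 0, spec$jitter)
      h <- spec$apex
      repeat {
        p1 <- (p0 + p2) / 2 + h * u + apex_jit
        arc <- .bezier(p0, p1, p2)
        if (streamline_length(arc) >= 20 || h > 200) break
        h <- h * 2
      }
      sls[[length(sls) + 1L]] <- arc
      edge_index <- c(edge_index, e)
    }
  }
  t <- tractogram(sls, affine = phantom$affine,
                  dim = dim(phantom$labels), voxsize = vs)
  t$edge_index <- edge_index
  t
}

# 0-based voxel set within `radius` mm of the polylines, as linear indices
.tube_voxels <- function(streamlines, dm, affine, radius, step = 0.5) {
  vs <- .affine_voxsize(affine)
  core <- integer()
  for (s in streamlines) {
    len <- streamline_length(s)
    npts <- max(2L, as.integer(ceiling(len / step)) + 1L)
    vox <- .voxel_of(affine, resample_streamline(s, npts))
    vox <- vox[.in_grid(vox, dm), , drop = FALSE]
    core <- c(core, vox[, 1L] + dm[1L] * (vox[, 2L] + dm[2L] * vox[, 3L]))
  }
  core <- unique(core)
  if (radius <= 0 || length(core) == 0L) return(core + 1L)
  rv <- floor(radius / vs)
  offs <- as.matrix(expand.grid(-rv[1L]:rv[1L], -rv[2L]:rv[2L],
                                -rv[3L]:rv[3L]))
  offs <- offs[sqrt(colSums((t(offs) * vs)^2)) <= radius, , drop = FALSE]
  cv <- cbind(core %% dm[1L],
              (core %/% dm[1L]) %% dm[2L],
              core %/% (dm[1L] * dm[2L]))
  out <- integer()
  for (r in seq_len(nrow(offs))) {
    v <- cv + matrix(offs[r, ], nrow(cv), 3L, byrow = TRUE)
    ok <- .in_grid(v, dm)
    out <- c(out, v[ok, 1L] + dm[1L] * (v[ok, 2L] + dm[2L] * v[ok, 3L]))
  }
  unique(out) + 1L
}

#' Simulate one subject's scalar map
#'
#' Background value everywhere; for each ground-truth edge present in the
#' subject (in the listed order, later edges overwriting earlier ones),
#' the voxels within `paint_radius` mm of the subject's bundle take the
#' edge's injected scalar value. Optional additive Gaussian noise.
#' Deterministic given (spec seed, subject).
#'
#' @param phantom the phantom [label_volume()].
#' @param spec the [phantom_spec()].
#' @param subject 1-based subject index.
#' @param tract optionally, the subject tractogram already simulated for
#'   this subject (must come from the same spec/subject).
#' @return numeric 3-D array.
#' @export
make_scalar_map <- function(phantom, spec, subject, tract = NULL) {
  if (is.null(tract))
    tract <- simulate_subject_tractogram(phantom, spec, subject)
  dm <- dim(phantom$labels)
  vol <- array(spec$background, dm)
  for (e in seq_len(nrow(spec$edges))) {
    sl <- tract$streamlines[tract$edge_index == e]
    if (length(sl) == 0L) next
    lin <- .tube_voxels(sl, dm, phantom$affine, spec$paint_radius)
    vol[lin] <- spec$scalar_values[e]
  }
  if (spec$noise_sd > 0) {
    set.seed((phantom_subject_seed(spec$seed, subject) + 104729L) %%
               2147483647L)
    vol <- vol + array(stats::rnorm(prod(dm), 0, spec$noise_sd), dm)
  }
  vol
}

#' Spherical lesion mask
#'
#' Voxels whose center lies within `radius` mm of `center`.
#'
#' @param phantom the phantom [label_volume()] (defines the grid).
#' @param center world coordinates (mm) of the sphere center.
#' @param radius radius in mm (> 0).
#' @return logical array; empty (with a warning) if the center is outside
#'   the grid.
#' @export
make_lesion_mask <- function(phantom, center, radius) {
  stopifnot(inherits(phantom, "label_volume"))
  if (radius <= 0) stop("radius must be > 0")
  dm <- dim(phantom$labels)
  cv <- .world_to_voxel(phantom$affine, rbind(center))
  if (!all(.in_grid(round(cv), dm))) {
    warning("lesion center outside the grid; returning an empty mask")
    return(array(FALSE, dm))
  }
  idx <- arrayInd(seq_len(prod(dm)), dm) - 1L
  w <- .voxel_to_world(phantom$affine, idx)
  d2 <- rowSums(sweep(w, 2L, as.numeric(center))^2)
  array(d2 <= radius^2, dm)
}

#' Injected loop and outlier streamlines
#'
#' Explicit artifact injectors for testing the bundle-cleaning stage:
#' `phantom_loop_streamline` winds `turns` full turns around the chord
#' midpoint (flagged as a loop when `turns > 1`);
#' `phantom_outlier_streamline` is an arc displaced `offset` mm
#' perpendicular to the chord.
#'
#' @param p0,p2 endpoint coordinates (mm).
#' @param turns number of full turns of the spiral.
#' @param offset perpendicular displacement in mm.
#' @param m number of points.
#' @return a streamline matrix.
#' @export
phantom_loop_streamline <- function(p0, p2, turns = 1.5, m = 120L) {
  chord <- p2 - p0
  u <- .perp_unit(chord)
  v <- c(chord[2L] * u[3L] - chord[3L] * u[2L],
         chord[3L] * u[1L] - chord[1L] * u[3L],
         chord[1L] * u[2L] - chord[2L] * u[1L])
  v <- v / sqrt(sum(v^2))
  tt <- seq(0, 1, length.out = m)
  ang <- 2 * pi * turns * tt
  r <- 5
  base <- outer(1 - tt, p0) + outer(tt, p2)
  base + outer(r * cos(ang) - r, u) + outer(r * sin(ang), v)
}

#' @rdname phantom_loop_streamline
#' @export
phantom_outlier_streamline <- function(p0, p2, offset = 30, m = 40L) {
  u <- .perp_unit(p2 - p0)
  shift <- offset * u
  .bezier(p0 + shift, (p0 + p2) / 2 + shift + 6 * u, p2 + shift, m = m)
}

#' Generate a full phantom dataset
#'
#' @param spec a [phantom_spec()].
#' @param nsubjects number of subjects.
#' @return list with `parcellation`, `wm_mask`, `tractograms` (length
#'   `nsubjects`), `scalars` (length `nsubjects`) and `ground_truth`
#'   (data frame of edges with presence, rate and injected value).
#' @export
make_phantom_dataset <- function(spec, nsubjects) {
  p <- make_phantom_parcellation(spec)
  tracts <- lapply(seq_len(nsubjects), function(s)
    simulate_subject_tractogram(p, spec, s))
  scalars <- lapply(seq_len(nsubjects), function(s)
    make_scalar_map(p, spec, s, tract = tracts[[s]]))
  gt <- data.frame(i = spec$edges[, 1L], j = spec$edges[, 2L],
                   presence = spec$presence, rate = spec$rate,
                   scalar = spec$scalar_values)
  list(parcellation = p, wm_mask = phantom_wm_mask(p),
       tractograms = tracts, scalars = scalars, ground_truth = gt)
}

#' Build an atlas from a phantom
#'
#' Convenience wrapper: generates `nsubjects` phantom tractograms and runs
#' the full dissection + atlas-construction pipeline.
#'
#' @param spec a [phantom_spec()].
#' @param nsubjects number of subjects.
#' @param c_min,n_bins consensus parameters.
#' @param clean run bundle cleaning (default TRUE).
#' @return list with `atlas`, plus everything from
#'   [make_phantom_dataset()].
#' @export
build_phantom_atlas <- function(spec, nsubjects, c_min = 0, n_bins = 10L,
                                clean = TRUE) {
  ds <- make_phantom_dataset(spec, nsubjects)
  atlas <- build_atlas_from_tractograms(ds$tractograms, ds$parcellation,
                                        scale = 1L, c_min = c_min,
                                        n_bins = n_bins, clean = clean)
  c(list(atlas = atlas), ds)
}
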