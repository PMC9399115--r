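#' Streamline geometry
#'
#' A streamline is an ordered polyline through white matter, stored as an
#' n x 3 numeric matrix of world-space coordinates in mm (RAS orientation).
#' These helpers provide the geometric primitives the dissection and atlas
#' construction stages are built on: geodesic (polyline) length, total
#' winding for loop detection, arc-length resampling, the minimum average
#' direct-flip (MDF) distance used by QuickBundles clustering, lossy
#' compression with a guaranteed maximum error, and point-wise application
#' of spatial transforms.
#'
#' @name streamline-geometry
NULL

#' Validate and coerce a streamline
#'
#' @param x an n x 3 matrix-like object of coordinates in mm.
#' @return a validated n x 3 numeric matrix.
#' @export
as_streamline <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L)
    stop("a streamline must be an n x 3 coordinate matrix")
  if (nrow(x) < 2L)
    stop("invalid streamline: fewer than 2 points")
  if (!all(is.finite(x)))
    stop("invalid streamline: non-finite coordinates")
  dimnames(x) <- NULL
  x
}

#' Geodesic length of a streamline
#'
#' Sum of Euclidean segment lengths along the polyline, in mm.
#'
#' @param s a streamline (n x 3 matrix, n >= 2).
#' @return length in mm (>= 0).
#' @export
streamline_length <- function(s) {
  s <- as_streamline(s)
  d <- diff(s)
  sum(sqrt(rowSums(d * d)))
}

#' Total winding of a streamline
#'
#' Sum of unsigned turning angles between consecutive segments, in degrees.
#' Zero-length segments are skipped. A streamline winding more than 360
#' degrees is treated as a loop by the bundle-cleaning stage.
#'
#' @param s a streamline; fewer than 3 points gives 0.
#' @return total turning in degrees (>= 0).
#' @seealso [is_loop()]
#' @export
total_winding <- function(s) {
  s <- as.matrix(s)
  storage.mode(s) <- "double"
  if (nrow(s) < 3L) return(0)
  d <- diff(s)
  len <- sqrt(rowSums(d * d))
  d <- d[len > 0, , drop = FALSE]
  if (nrow(d) < 2L) return(0)
  a <- d[-nrow(d), , drop = FALSE]
  b <- d[-1L, , drop = FALSE]
  cosang <- rowSums(a * b) /
    (sqrt(rowSums(a * a)) * sqrt(rowSums(b * b)))
  cosang <- pmin(1, pmax(-1, cosang))
  sum(acos(cosang)) * 180 / pi
}

#' Loop test
#'
#' @param s a streamline.
#' @param threshold winding threshold in degrees; strictly greater flags a
#'   loop.
#' @return logical.
#' @export
is_loop <- function(s, threshold = 360) {
  total_winding(s) > threshold
}

#' Resample a streamline to n equally spaced points
#'
#' Points are placed at equal arc-length intervals along the polyline;
#' both endpoints are preserved. Resampling can only shorten the polyline
#' (chords never exceed the arcs they replace).
#'
#' @param s a streamline.
#' @param n number of output points (>= 2).
#' @return an n x 3 streamline.
#' @export
resample_streamline <- function(s, n) {
  s <- as_streamline(s)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  seg <- sqrt(rowSums(diff(s)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0)   # fully degenerate: all points coincide
    return(matrix(s[1L, ], nrow = n, ncol = 3L, byrow = TRUE))
  keep <- c(TRUE, seg > 0)
  cs <- cum[keep]
  pts <- s[keep, , drop = FALSE]
  tt <- seq(0, total, length.out = n)
  out <- vapply(1:3, function(k) {
    stats::approx(cs, pts[, k], xout = tt, rule = 2)$y
  }, numeric(n))
  out[1L, ] <- s[1L, ]
  out[n, ] <- s[nrow(s), ]
  out
}

#' Minimum average direct-flip (MDF) distance
#'
#' The QuickBundles metric: both streamlines are resampled to `n` points and
#' the mean point-wise Euclidean distance is taken in the direct and the
#' reversed ordering; the smaller of the two is returned. The distance is
#' symmetric, non-negative and zero for identical or exactly reversed
#' streamlines.
#'
#' @param a,b streamlines.
#' @param n resampling point count (default 12, common QuickBundles
#'   practice).
#' @return distance in mm.
#' @export
mdf_distance <- function(a, b, n = 12L) {
  ra <- resample_streamline(a, n)
  rb <- resample_streamline(b, n)
  .mdf_resampled(ra, rb)
}

# MDF on already-resampled point matrices of equal row count.
.mdf_resampled <- function(ra, rb) {
  d1 <- ra - rb
  d2 <- ra - rb[nrow(rb):1L, , drop = FALSE]
  min(mean(sqrt(rowSums(d1 * d1))), mean(sqrt(rowSums(d2 * d2))))
}

# Distances from points (m x 3) to the segment a--b; degenerate segments
# fall back to point distance.
.point_segment_distance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab * ab)
  rel <- sweep(p, 2L, a)
  if (denom == 0) return(sqrt(rowSums(rel * rel)))
  tt <- pmin(1, pmax(0, as.vector(rel %*% ab) / denom))
  proj <- outer(tt, ab)
  d <- rel - proj
  sqrt(rowSums(d * d))
}

#' Compress a streamline with a bounded error
#'
#' Endpoint-anchored point removal (recursive farthest-point splitting):
#' the result is a subset of the original points including both endpoints,
#' and every removed point lies within `max_error` mm of the compressed
#' polyline. The default of 0.2 mm is the setting used for compressed
#' whole-brain tractograms.
#'
#' @param s a streamline.
#' @param max_error maximum allowed point-to-polyline deviation in mm.
#' @return the compressed streamline.
#' @export
compress_streamline <- function(s, max_error = 0.2) {
  s <- as_streamline(s)
  if (!is.finite(max_error) || max_error <= 0)
    stop("max_error must be > 0")
  np <- nrow(s)
  if (np == 2L) return(s)
  keep <- logical(np)
  keep[c(1L, np)] <- TRUE
  stack <- list(c(1L, np))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1L]; j <- rng[2L]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- .point_segment_distance(s[mid, , drop = FALSE], s[i, ], s[j, ])
    k <- which.max(d)
    if (d[k] > max_error) {
      split <- mid[k]
      keep[split] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, split)
      stack[[length(stack) + 1L]] <- c(split, j)
    }
  }
  s[keep, , drop = FALSE]
}

#' Spatial transform (affine plus optional displacement field)
#'
#' Represents the mapping p' = A p + D(A p): an affine component followed by
#' an additive displacement sampled with trilinear interpolation from a
#' vector field defined on its own grid (displacements in mm).
#'
#' @param affine invertible 4 x 4 matrix.
#' @param displacement optional 4-D array `[nx, ny, nz, 3]` of mm
#'   displacements.
#' @param displacement_affine 4 x 4 voxel-to-world affine of the
#'   displacement grid (required when `displacement` is given).
#' @return an object of class `spatial_transform`.
#' @export
spatial_transform <- function(affine = diag(4), displacement = NULL,
                              displacement_affine = NULL) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4 x 4 matrix")
  if (!is.null(displacement)) {
    if (length(dim(displacement)) != 4L || dim(displacement)[4L] != 3L)
      stop("displacement must be an [nx, ny, nz, 3] array")
    if (is.null(displacement_affine))
      stop("displacement_affine is required with a displacement field")
    displacement_affine <- as.matrix(displacement_affine)
    if (!all(is.finite(displacement)))
      stop("displacement field contains non-finite values")
  }
  structure(list(affine = affine, displacement = displacement,
                 displacement_affine = displacement_affine),
            class = "spatial_transform")
}

# Apply a 4x4 affine to an n x 3 point matrix.
.apply_affine <- function(affine, pts) {
  out <- pts %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4L], nrow(pts), 3L, byrow = TRUE)
  out
}

# Trilinear sampling of a [nx,ny,nz,3] field at continuous 0-based voxel
# coordinates (n x 3). Returns list(values = n x 3, inside = logical n).
.sample_field <- function(field, vox) {
  dm <- dim(field)[1:3]
  f0 <- floor(vox)
  inside <- f0[, 1L] >= 0 & f0[, 2L] >= 0 & f0[, 3L] >= 0 &
    (f0[, 1L] + 1) <= (dm[1L] - 1) & (f0[, 2L] + 1) <= (dm[2L] - 1) &
    (f0[, 3L] + 1) <= (dm[3L] - 1)
  # points exactly on the upper boundary are inside too
  on_hi <- vox[, 1L] <= (dm[1L] - 1) & vox[, 2L] <= (dm[2L] - 1) &
    vox[, 3L] <= (dm[3L] - 1) & f0[, 1L] >= 0 & f0[, 2L] >= 0 & f0[, 3L] >= 0
  hi_fix <- on_hi & !inside
  if (any(hi_fix))
    f0[hi_fix, ] <- pmin(f0[hi_fix, , drop = FALSE],
                         matrix(dm - 2, sum(hi_fix), 3L, byrow = TRUE))
  inside <- inside | on_hi
  vals <- matrix(0, nrow(vox), 3L)
  if (any(inside)) {
    v <- vox[inside, , drop = FALSE]
    g <- f0[inside, , drop = FALSE]
    fr <- v - g
    acc <- matrix(0, nrow(v), 3L)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fr[, 1L] else 1 - fr[, 1L]) *
        (if (dy) fr[, 2L] else 1 - fr[, 2L]) *
        (if (dz) fr[, 3L] else 1 - fr[, 3L])
      idx <- cbind(g[, 1L] + dx + 1L, g[, 2L] + dy + 1L, g[, 3L] + dz + 1L)
      for (k in 1:3) acc[, k] <- acc[, k] + w * field[cbind(idx, k)]
    }
    vals[inside, ] <- acc
  }
  list(values = vals, inside = inside)
}

#' Apply a spatial transform to points
#'
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param xf a [spatial_transform()].
#' @param on_missing what to do for points outside the displacement-field
#'   support: `"error"` (default) or `"zero"` (zero-displacement fallback).
#' @return transformed n x 3 matrix.
#' @export
apply_transform_points <- function(pts, xf, on_missing = c("error", "zero")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(xf, "spatial_transform"))
  pts <- as.matrix(pts)
  q <- .apply_affine(xf$affine, pts)
  if (!is.null(xf$displacement)) {
    vox <- .world_to_voxel(xf$displacement_affine, q)
    smp <- .sample_field(xf$displacement, vox)
    if (!all(smp$inside) && on_missing == "error")
      stop(sum(!smp$inside),
           " point(s) outside the displacement-field support")
    q <- q + smp$values
  }
  q
}

#' Apply a spatial transform to a whole tractogram
#'
#' Streamline count and per-streamline point counts are preserved; only the
#' coordinates change. Grid metadata is carried over unchanged.
#'
#' @param t a [tractogram()].
#' @param xf a [spatial_transform()].
#' @param on_missing see [apply_transform_points()].
#' @return the transformed tractogram.
#' @export
transform_points <- function(t, xf, on_missing = c("error", "zero")) {
  stopifnot(inherits(t, "tractogram"))
  on_missing <- match.arg(on_missing)
  t$streamlines <- lapply(t$streamlines, apply_transform_points,
                          xf = xf, on_missing = on_missing)
  t
}
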