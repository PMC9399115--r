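#' Tractogram dissection
#'
#' Turns a whole-brain tractogram plus a labeled gray-matter parcellation
#' into cleaned region-pair white-matter bundles and subject-level
#' number-of-streamlines (NOS) and mean-length matrices. Streamlines are
#' kept if their geodesic length lies within bounds (20-200 mm by default),
#' assigned to the unordered pair of regions containing their endpoints,
#' and each resulting bundle is cleaned of loops and spatial outliers.
#'
#' @name dissection
NULL

# out[v] = a[v + off]; zero-filled at the borders
.shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0L, d)
  src_lo <- pmax(1L, 1L + off)
  src_hi <- pmin(d, d + off)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - off
  dst_hi <- src_hi - off
  out[dst_lo[1L]:dst_hi[1L], dst_lo[2L]:dst_hi[2L], dst_lo[3L]:dst_hi[3L]] <-
    a[src_lo[1L]:src_hi[1L], src_lo[2L]:src_hi[2L], src_lo[3L]:src_hi[3L]]
  out
}

#' Dilate a parcellation into the white matter
#'
#' Unlabeled voxels inside `wm_mask` whose center lies within `radius` mm
#' (Euclidean, voxel-center to voxel-center) of a labeled voxel take the
#' label of the nearest labeled voxel. Originally labeled voxels are never
#' relabeled, and nothing outside the white-matter mask gains a label.
#' Distance ties are broken toward the lower region code.
#'
#' @param p a [label_volume()].
#' @param radius dilation radius in mm (>= 0); the conventional tractography
#'   termination-mask setting is 2 mm.
#' @param wm_mask logical/0-1 array on the same grid as `p`.
#' @return the dilated [label_volume()].
#' @export
dilate_parcellation <- function(p, radius = 2, wm_mask) {
  stopifnot(inherits(p, "label_volume"))
  if (radius < 0) stop("radius must be >= 0")
  wm_mask <- as.array(wm_mask) != 0
  if (!all(dim(wm_mask) == dim(p$labels)))
    stop("wm_mask grid does not match the parcellation grid")
  if (radius == 0) return(p)
  vs <- .affine_voxsize(p$affine)
  rv <- floor(radius / vs)
  offs <- as.matrix(expand.grid(x = -rv[1L]:rv[1L], y = -rv[2L]:rv[2L],
                                z = -rv[3L]:rv[3L]))
  d <- sqrt(colSums((t(offs) * vs)^2))
  sel <- d <= radius & d > 0
  offs <- offs[sel, , drop = FALSE]
  d <- d[sel]
  assigned <- p$labels
  eligible <- wm_mask & p$labels == 0L
  for (dist in sort(unique(d))) {
    grp <- which(d == dist)
    cand <- array(0L, dim(p$labels))
    for (g in grp) {
      sh <- .shift_array(p$labels, offs[g, ])
      upd <- sh > 0L & (cand == 0L | sh < cand)
      cand[upd] <- sh[upd]
    }
    sel <- eligible & assigned == 0L & cand > 0L
    assigned[sel] <- cand[sel]
  }
  label_volume(assigned, p$affine, p$table)
}

#' Assign a streamline to its endpoint region pair
#'
#' Looks up the parcellation label at the voxels containing the first and
#' last points of the streamline (exact voxel, no search radius). Returns
#' the sorted pair when both labels are non-zero and distinct, otherwise
#' `NULL` (unassigned): background endpoints and same-region
#' (self-connection) streamlines are excluded.
#'
#' @param s a streamline.
#' @param p a [label_volume()] (normally dilated, see
#'   [dilate_parcellation()]).
#' @param warn warn when an endpoint falls outside the grid.
#' @return integer vector `c(i, j)` with `i < j`, or `NULL`.
#' @export
assign_endpoints <- function(s, p, warn = TRUE) {
  s <- as_streamline(s)
  stopifnot(inherits(p, "label_volume"))
  ends <- s[c(1L, nrow(s)), , drop = FALSE]
  vox <- .voxel_of(p$affine, ends)
  if (!all(.in_grid(vox, dim(p$labels)))) {
    if (warn) warning("streamline endpoint outside the parcellation grid")
    return(NULL)
  }
  lab <- p$labels[vox + 1L]
  if (any(lab == 0L) || lab[1L] == lab[2L]) return(NULL)
  sort(lab)
}

#' QuickBundles streamline clustering
#'
#' Single-pass clustering with the minimum average direct-flip (MDF)
#' metric: streamlines are resampled to `n` points, and each streamline
#' joins the first cluster whose centroid lies closer than `threshold` mm,
#' otherwise it founds a new cluster. Centroids are running means of the
#' flip-aligned resampled streamlines. The clusters partition the input.
#'
#' @param bundle list of streamlines.
#' @param threshold MDF distance threshold in mm (> 0).
#' @param n resampling point count.
#' @return list with `clusters` (list of index vectors) and `centroids`
#'   (list of n x 3 matrices).
#' @export
quickbundles <- function(bundle, threshold, n = 12L) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  if (length(bundle) == 0L)
    return(list(clusters = list(), centroids = list()))
  rs <- lapply(bundle, resample_streamline, n = n)
  clusters <- list()
  sums <- list()
  for (i in seq_along(rs)) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      cen <- sums[[k]] / length(clusters[[k]])
      direct <- mean(sqrt(rowSums((rs[[i]] - cen)^2)))
      flip <- mean(sqrt(rowSums((rs[[i]][n:1L, , drop = FALSE] - cen)^2)))
      if (min(direct, flip) < threshold) {
        aligned <- if (flip < direct) rs[[i]][n:1L, , drop = FALSE] else rs[[i]]
        clusters[[k]] <- c(clusters[[k]], i)
        sums[[k]] <- sums[[k]] + aligned
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- i
      sums[[length(sums) + 1L]] <- rs[[i]]
    }
  }
  centroids <- Map(function(s, cl) s / length(cl), sums, clusters)
  list(clusters = clusters, centroids = centroids)
}

#' Clean a bundle of loops and spatial outliers
#'
#' Two-stage outlier rejection. Stage 1 removes streamlines winding more
#' than 360 degrees (loops). Stage 2 clusters the survivors with
#' [quickbundles()] at a decreasing threshold sequence (a cluster tree),
#' scores each streamline by its normalized tree length -- the mean over
#' levels of the size fraction of its cluster -- and removes streamlines
#' scoring below `tree_threshold`. Spatially isolated streamlines sit in
#' singleton clusters at every level and score near 1/m. Bundles of two or
#' fewer streamlines skip stage 2.
#'
#' @param bundle list of streamlines.
#' @param tree_threshold score cut in (0, 1); default 0.2.
#' @param qb_threshold coarsest clustering threshold in mm; levels are
#'   `qb_threshold / c(1, 2, 4)`.
#' @param n resampling point count for the metric.
#' @return the filtered bundle (a subset of the input).
#' @export
clean_bundle <- function(bundle, tree_threshold = 0.2, qb_threshold = 10,
                         n = 12L) {
  if (tree_threshold <= 0 || tree_threshold >= 1)
    stop("tree_threshold must be in (0, 1)")
  kept <- bundle[!vapply(bundle, is_loop, logical(1L))]
  m <- length(kept)
  if (m <= 2L) return(kept)
  thresholds <- qb_threshold / c(1, 2, 4)
  score <- numeric(m)
  for (thr in thresholds) {
    qb <- quickbundles(kept, thr, n = n)
    for (cl in qb$clusters) score[cl] <- score[cl] + length(cl) / m
  }
  score <- score / length(thresholds)
  kept[score >= tree_threshold]
}

#' Bundle set container
#'
#' @param pairs named list keyed by `"i_j"` region pairs, each a list of
#'   streamlines.
#' @param scale parcellation scale identifier.
#' @return an object of class `bundle_set`.
#' @export
bundle_set <- function(pairs, scale = 1L) {
  structure(list(scale = scale, pairs = pairs), class = "bundle_set")
}

#' @export
print.bundle_set <- function(x, ...) {
  cat("bundle_set (scale ", x$scale, "): ", length(x$pairs),
      " region pairs, ", sum(lengths(x$pairs)), " streamlines\n", sep = "")
  invisible(x)
}

#' Dissect a tractogram into region-pair bundles
#'
#' Applies the length filter (inclusive bounds), assigns each surviving
#' streamline to its endpoint region pair, cleans each bundle with
#' [clean_bundle()], and computes the subject NOS and mean-length matrices
#' from the cleaned bundles.
#'
#' @param t a [tractogram()].
#' @param p a (dilated) [label_volume()] on a grid covering the
#'   streamlines.
#' @param min_len,max_len length bounds in mm (defaults 20 and 200).
#' @param scale parcellation scale identifier carried into the result.
#' @param clean run the outlier-rejection stage (default TRUE).
#' @param tree_threshold,qb_threshold see [clean_bundle()].
#' @return list with `bundles` (a [bundle_set()]) and `connectome`
#'   (a [subject_connectome()]).
#' @export
extract_bundles <- function(t, p, min_len = 20, max_len = 200, scale = 1L,
                            clean = TRUE, tree_threshold = 0.2,
                            qb_threshold = 10) {
  stopifnot(inherits(t, "tractogram"), inherits(p, "label_volume"))
  codes <- p$table$code
  n <- length(codes)
  pairs <- list()
  n_outside <- 0L
  for (s in t$streamlines) {
    len <- streamline_length(s)
    if (len < min_len || len > max_len) next
    pr <- withCallingHandlers(
      assign_endpoints(s, p, warn = TRUE),
      warning = function(w) {
        n_outside <<- n_outside + 1L
        invokeRestart("muffleWarning")
      })
    if (is.null(pr)) next
    key <- pair_key(pr[1L], pr[2L])
    pairs[[key]] <- c(pairs[[key]], list(s))
  }
  if (n_outside > 0L)
    warning(n_outside, " streamline(s) had endpoints outside the grid")
  nos <- matrix(0, n, n)
  lens <- matrix(0, n, n)
  cleaned <- list()
  for (key in names(pairs)) {
    b <- if (clean) {
      clean_bundle(pairs[[key]], tree_threshold = tree_threshold,
                   qb_threshold = qb_threshold)
    } else pairs[[key]]
    if (length(b) == 0L) next
    cleaned[[key]] <- b
    ij <- .parse_pair_key(key)
    a <- match(ij[1L], codes)
    z <- match(ij[2L], codes)
    nos[a, z] <- nos[z, a] <- length(b)
    ml <- mean(vapply(b, streamline_length, numeric(1L)))
    lens[a, z] <- lens[z, a] <- ml
  }
  list(bundles = bundle_set(cleaned, scale = scale),
       connectome = subject_connectome(nos, lens, codes))
}
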