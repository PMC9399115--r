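#' Atlas construction
#'
#' Aggregates per-subject region-pair bundles into tract density images
#' (TDIs), spatial probabilistic anatomical maps (SPAMs), group
#' connectivity matrices, and a final atlas whose bundle list is fixed by
#' distance-dependent consensus thresholding.
#'
#' @name atlas-build
NULL

# Exact voxel traversal of a polyline: in continuous voxel coordinates,
# find every crossing of a voxel-boundary plane (half-integer planes,
# since indices address voxel centers), then evaluate the polyline at the
# midpoints between consecutive crossings -- each midpoint lies strictly
# inside one traversed voxel. Returns the deduplicated 0-based voxel
# index matrix.
.polyline_voxels <- function(s, affine) {
  v <- .world_to_voxel(affine, s)
  n <- nrow(v)
  ts <- as.numeric(seq_len(n) - 1L)
  cross <- numeric(0)
  for (i in seq_len(n - 1L)) {
    a <- v[i, ]
    b <- v[i + 1L, ]
    for (ax in 1:3) {
      if (b[ax] == a[ax]) next
      lo <- min(a[ax], b[ax])
      hi <- max(a[ax], b[ax])
      k0 <- ceiling(lo - 0.5)
      k1 <- floor(hi - 0.5)
      if (k1 < k0) next
      planes <- (k0:k1) + 0.5
      cross <- c(cross, (i - 1L) + (planes - a[ax]) / (b[ax] - a[ax]))
    }
  }
  tt <- sort(unique(c(ts, cross)))
  samp <- c(ts, (tt[-1L] + tt[-length(tt)]) / 2)
  pos <- vapply(1:3, function(ax)
    stats::approx(ts, v[, ax], xout = samp)$y, numeric(length(samp)))
  vox <- unique(round(pos))
  storage.mode(vox) <- "integer"
  vox
}

#' Tract density image of a bundle
#'
#' Counts, per voxel, the number of streamlines traversing it. Traversal
#' is geometric: the exact set of voxels whose cube the polyline passes
#' through, obtained by subdividing each segment at its voxel-boundary
#' crossings. Visited voxels are deduplicated per streamline, so each
#' streamline increments a voxel at most once.
#'
#' @param bundle list of streamlines (world mm, in the grid's space).
#' @param dim grid dimensions (3 integers).
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param pair optional region-code pair the bundle connects.
#' @param subject optional subject identifier.
#' @return an object of class `tdi_volume` with fields `counts`, `affine`,
#'   `dim`, `pair`, `subject`.
#' @export
compute_tdi <- function(bundle, dim, affine, pair = NULL, subject = NULL) {
  dim <- as.integer(dim)
  counts <- array(0L, dim)
  n_out <- 0L
  for (s in bundle) {
    s <- as_streamline(s)
    vox <- .polyline_voxels(s, affine)
    ok <- .in_grid(vox, dim)
    if (!all(ok)) {
      n_out <- n_out + 1L
      vox <- vox[ok, , drop = FALSE]
    }
    if (nrow(vox) == 0L) next
    lin <- unique(vox[, 1L] + dim[1L] * (vox[, 2L] + dim[2L] * vox[, 3L]))
    counts[lin + 1L] <- counts[lin + 1L] + 1L
  }
  if (n_out > 0L)
    warning(n_out, " streamline(s) had samples outside the grid (ignored)")
  structure(list(counts = counts, affine = as.matrix(affine), dim = dim,
                 pair = pair, subject = subject),
            class = "tdi_volume")
}

#' Spatial probabilistic anatomical map of a bundle
#'
#' Binarizes the per-subject TDIs at one streamline, sums the binary masks
#' across subjects, and keeps the voxels present in at least one subject.
#' The stored count at a voxel is the number of subjects whose bundle
#' traverses it; dividing by `nsubjects` gives the voxel-wise probability.
#' The mean TDI averages raw counts over all `nsubjects` (subjects without
#' the bundle contribute zeros).
#'
#' @param tdis list of `tdi_volume` objects for one pair, one per subject
#'   that has the bundle; all on the same grid.
#' @param nsubjects total number of subjects S (>= length(tdis)).
#' @return list with `spam` (class `spam`: fields `pair`, `voxels` -- an
#'   N x 4 integer matrix of 0-based x, y, z indices plus subject count --
#'   `nsubjects`, `dim`, `affine`) and `mean_tdi` (array).
#' @export
build_spam <- function(tdis, nsubjects = length(tdis)) {
  if (length(tdis) == 0L) stop("at least one TDI is required")
  if (nsubjects < length(tdis))
    stop("nsubjects must be >= the number of TDIs supplied")
  dm <- tdis[[1L]]$dim
  aff <- tdis[[1L]]$affine
  for (td in tdis) {
    if (!all(td$dim == dm) || !isTRUE(all.equal(td$affine, aff)))
      stop("all TDIs must share the same grid")
  }
  bin_sum <- Reduce(`+`, lapply(tdis, function(x) (x$counts >= 1L) * 1L))
  mean_tdi <- Reduce(`+`, lapply(tdis, function(x) x$counts)) / nsubjects
  idx <- which(bin_sum >= 1L)
  vox <- arrayInd(idx, dm) - 1L
  voxels <- cbind(vox, bin_sum[idx])
  storage.mode(voxels) <- "integer"
  colnames(voxels) <- c("x", "y", "z", "count")
  spam <- structure(list(pair = tdis[[1L]]$pair, voxels = voxels,
                         nsubjects = as.integer(nsubjects), dim = dm,
                         affine = aff),
                    class = "spam")
  list(spam = spam, mean_tdi = mean_tdi)
}

#' Construct a SPAM from a sparse voxel table
#'
#' @param pair region-code pair the bundle connects.
#' @param voxels N x 4 integer matrix: 0-based voxel x, y, z indices and
#'   per-voxel subject counts in 1..nsubjects.
#' @param nsubjects total number of subjects S.
#' @param dim grid dimensions.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return an object of class `spam`.
#' @export
spam <- function(pair, voxels, nsubjects, dim, affine) {
  voxels <- as.matrix(voxels)
  storage.mode(voxels) <- "integer"
  colnames(voxels) <- c("x", "y", "z", "count")
  dim <- as.integer(dim)
  if (any(voxels[, "count"] < 1L) || any(voxels[, "count"] > nsubjects))
    stop("voxel counts must lie in 1..nsubjects")
  if (!all(.in_grid(voxels[, 1:3, drop = FALSE], dim)))
    stop("voxel indices outside the grid")
  if (anyDuplicated(voxels[, 1:3, drop = FALSE]))
    stop("duplicate voxels in SPAM")
  structure(list(pair = sort(as.integer(pair)), voxels = voxels,
                 nsubjects = as.integer(nsubjects), dim = dim,
                 affine = as.matrix(affine)),
            class = "spam")
}

#' Group connectivity matrices
#'
#' From a list of subject connectomes on a common region set, computes the
#' consistency matrix (number of subjects with at least one streamline for
#' the connection), the mean NOS over all subjects, and the mean length
#' over the subjects that have the connection (0 where none does).
#'
#' @param connectomes list of [subject_connectome()] objects.
#' @return an object of class `group_matrices` with fields `consistency`,
#'   `numbStlines`, `length`, `nsubjects`, `codes`.
#' @export
group_connectivity <- function(connectomes) {
  S <- length(connectomes)
  if (S < 1L) stop("at least one subject is required")
  codes <- connectomes[[1L]]$codes
  for (sc in connectomes)
    if (!identical(sc$codes, codes))
      stop("all subjects must share the same region set")
  cons <- Reduce(`+`, lapply(connectomes, function(sc) (sc$nos > 0) * 1L))
  nos_mean <- Reduce(`+`, lapply(connectomes, function(sc) sc$nos)) / S
  len_sum <- Reduce(`+`, lapply(connectomes, function(sc) sc$length))
  len_mean <- ifelse(cons > 0, len_sum / pmax(cons, 1L), 0)
  storage.mode(cons) <- "integer"
  structure(list(consistency = cons, numbStlines = nos_mean,
                 length = len_mean, nsubjects = as.integer(S),
                 codes = codes),
            class = "group_matrices")
}

#' Distance-dependent consensus thresholding
#'
#' Fixes the atlas bundle list so the group network matches the average
#' subject connection density while preserving the connection-length
#' distribution, separately for intra- and inter-hemispheric connections:
#'
#' 1. Candidates are pairs present in at least `ceil(c_min * S)` subjects
#'    (and at least one subject).
#' 2. Candidates split into intra-hemispheric (both regions L or both R)
#'    and inter-hemispheric (all others, including midline) classes.
#' 3. Within each class, candidates are partitioned into `n_bins`
#'    equal-count bins of group mean length.
#' 4. Each bin's target is the rounded mean, over subjects, of the number
#'    of that subject's existing connections of the class whose group mean
#'    length falls in the bin.
#' 5. The target most-consistent candidates are kept per bin (capped at
#'    the bin size); ties broken by higher consistency, then higher mean
#'    NOS, then lexicographic region codes. The retained set is the union
#'    over bins and classes.
#'
#' @param connectomes list of [subject_connectome()] objects.
#' @param group the [group_connectivity()] result for the same subjects.
#' @param regions data frame with `code` and `hemisphere` columns.
#' @param c_min minimum subject fraction in `[0, 1]` (default 0).
#' @param n_bins number of length bins (default 10).
#' @return two-column integer matrix of retained region-code pairs
#'   (i < j), ordered lexicographically.
#' @export
consensus_threshold <- function(connectomes, group, regions, c_min = 0,
                                n_bins = 10L) {
  S <- group$nsubjects
  if (S == 0L || length(connectomes) != S)
    stop("connectomes must match the group matrices' subject count")
  if (c_min < 0 || c_min > 1) stop("c_min must be in [0, 1]")
  n_bins <- max(1L, as.integer(n_bins))
  codes <- group$codes
  hemi <- regions$hemisphere[match(codes, regions$code)]
  if (anyNA(hemi)) stop("regions table does not cover all matrix codes")
  n <- length(codes)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cons <- group$consistency[ut]
  min_cons <- max(1L, .frac_to_count(c_min, S))
  is_intra <- hemi[ut[, 1L]] == hemi[ut[, 2L]] &
    hemi[ut[, 1L]] %in% c("L", "R")
  retained <- matrix(integer(), 0L, 2L)
  for (cls in c(TRUE, FALSE)) {
    in_cls <- is_intra == cls
    cand <- which(in_cls & cons >= min_cons)
    if (length(cand) == 0L) next
    ci <- codes[ut[cand, 1L]]
    cj <- codes[ut[cand, 2L]]
    clen <- group$length[ut[cand, , drop = FALSE]]
    ccons <- cons[cand]
    cnos <- group$numbStlines[ut[cand, , drop = FALSE]]
    nb <- min(n_bins, length(cand))
    ord <- order(clen, ci, cj)
    bin <- integer(length(cand))
    bin[ord] <- ceiling(seq_along(cand) * nb / length(cand))
    upper <- vapply(seq_len(nb), function(b) max(clen[bin == b]),
                    numeric(1L))
    # per-subject bin occupancy of existing connections of this class;
    # a connection that is itself a candidate takes its candidate bin
    # (robust to tied lengths), others fall back to the length interval
    bin_of_pair <- integer(length(cons))
    bin_of_pair[cand] <- bin
    occupancy <- matrix(0, S, nb)
    cls_pairs <- which(in_cls)
    for (s in seq_len(S)) {
      nos_s <- connectomes[[s]]$nos[ut[cls_pairs, , drop = FALSE]]
      have <- cls_pairs[nos_s > 0]
      if (length(have) == 0L) next
      b <- bin_of_pair[have]
      fb <- b == 0L
      if (any(fb)) {
        lens <- group$length[ut[have[fb], , drop = FALSE]]
        b[fb] <- pmin(nb, findInterval(lens, upper, left.open = TRUE) + 1L)
      }
      occupancy[s, ] <- tabulate(b, nbins = nb)
    }
    target <- round(colMeans(occupancy))
    for (b in seq_len(nb)) {
      members <- which(bin == b)
      k <- min(length(members), target[b])
      if (k == 0L) next
      pick <- members[order(-ccons[members], -cnos[members], ci[members],
                            cj[members])][seq_len(k)]
      retained <- rbind(retained,
                        cbind(ci[pick], cj[pick]))
    }
  }
  retained <- retained[order(retained[, 1L], retained[, 2L]), ,
                       drop = FALSE]
  storage.mode(retained) <- "integer"
  colnames(retained) <- c("i", "j")
  retained
}

#' Assemble an atlas model
#'
#' Combines header metadata, group matrices and SPAMs into a validated
#' atlas. A SPAM must exist for every retained pair; SPAMs for pairs
#' outside the retained set are dropped.
#'
#' @param header list with `nsubjects`, `dim`, `voxsize`, `affine` and
#'   `regions` (a region table as in [label_volume()]).
#' @param group a `group_matrices` object.
#' @param spams list of `spam` objects (named by `"i_j"` key, or with
#'   `pair` fields set).
#' @param retained two-column matrix of retained region-code pairs.
#' @return an object of class `atlas_model`.
#' @export
assemble_atlas <- function(header, group, spams, retained) {
  stopifnot(inherits(group, "group_matrices"))
  if (is.null(names(spams)) && length(spams) > 0L)
    names(spams) <- vapply(spams, function(sp)
      pair_key(sp$pair[1L], sp$pair[2L]), character(1L))
  retained <- as.matrix(retained)
  keys <- if (nrow(retained)) pair_key(retained[, 1L], retained[, 2L])
          else character()
  missing <- setdiff(keys, names(spams))
  if (length(missing))
    stop("missing SPAM for retained pair(s): ",
         paste(missing, collapse = ", "))
  spams <- spams[keys]
  for (sp in spams) {
    if (any(sp$voxels[, "count"] < 1L) ||
        any(sp$voxels[, "count"] > header$nsubjects))
      stop("SPAM counts must lie in 1..nsubjects")
  }
  if (!all(group$codes %in% header$regions$code))
    stop("header region table does not cover all matrix codes")
  structure(list(header = header, matrices = group, spams = spams,
                 retained = retained),
            class = "atlas_model")
}

#' Number of bundles in an atlas
#' @param a an `atlas_model`.
#' @return integer bundle count.
#' @export
n_bundles <- function(a) {
  stopifnot(inherits(a, "atlas_model"))
  length(a$spams)
}

#' @export
print.atlas_model <- function(x, ...) {
  cat("atlas_model:", nrow(x$header$regions), "regions,", n_bundles(x),
      "bundles,", x$header$nsubjects, "subjects\n")
  invisible(x)
}

#' Build an atlas from per-subject tractograms
#'
#' End-to-end convenience pipeline: dissect each subject's tractogram with
#' [extract_bundles()], compute group matrices, fix the bundle list with
#' [consensus_threshold()], compute per-pair TDIs and SPAMs, and assemble
#' the atlas on the parcellation grid.
#'
#' @param tractograms list of [tractogram()] objects, one per subject.
#' @param parcellation a (dilated) [label_volume()].
#' @param scale parcellation scale identifier.
#' @param c_min,n_bins consensus parameters, see [consensus_threshold()].
#' @param min_len,max_len,clean dissection parameters, see
#'   [extract_bundles()].
#' @return an `atlas_model`.
#' @export
build_atlas_from_tractograms <- function(tractograms, parcellation,
                                         scale = 1L, c_min = 0,
                                         n_bins = 10L, min_len = 20,
                                         max_len = 200, clean = TRUE) {
  S <- length(tractograms)
  res <- lapply(tractograms, extract_bundles, p = parcellation,
                min_len = min_len, max_len = max_len, scale = scale,
                clean = clean)
  connectomes <- lapply(res, function(r) r$connectome)
  group <- group_connectivity(connectomes)
  retained <- consensus_threshold(connectomes, group, parcellation$table,
                                  c_min = c_min, n_bins = n_bins)
  dm <- dim(parcellation$labels)
  aff <- parcellation$affine
  spams <- list()
  if (nrow(retained)) {
    for (r in seq_len(nrow(retained))) {
      key <- pair_key(retained[r, 1L], retained[r, 2L])
      tdis <- list()
      for (s in seq_len(S)) {
        b <- res[[s]]$bundles$pairs[[key]]
        if (is.null(b)) next
        tdis[[length(tdis) + 1L]] <-
          compute_tdi(b, dm, aff, pair = retained[r, ], subject = s)
      }
      spams[[key]] <- build_spam(tdis, nsubjects = S)$spam
    }
  }
  header <- list(nsubjects = S, dim = dm,
                 voxsize = .affine_voxsize(aff), affine = aff,
                 regions = parcellation$table, scale = scale)
  assemble_atlas(header, group, spams, retained)
}
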