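#' Applying an atlas to user volumes
#'
#' Once individual scalar maps (FA, MD, quantitative T1, ...) or lesion
#' masks are warped to the atlas grid, the atlas turns them into
#' connection-level quantities without any tractography: scalar-weighted
#' connectivity matrices, ROI bundle queries, union masks and lesion
#' "dysconnectome" reports. No resampling happens here -- inputs must
#' already live on the atlas grid, and a grid mismatch is an error.
#'
#' @name atlas-apply
NULL

# integer subject threshold for a fractional consistency cut; the small
# slack keeps ceil() exact for products like 0.1 * 30
.frac_to_count <- function(frac, S) {
  as.integer(ceiling(frac * S - 1e-9))
}

.check_grid <- function(a, values) {
  if (!all(dim(values)[1:3] == a$header$dim))
    stop("input grid does not match the atlas grid (no silent resampling)")
}

#' Thresholded voxel set of a bundle
#'
#' Voxels of the bundle's SPAM whose probability count/S is at least
#' `p_thr` (inclusive).
#'
#' @param a an `atlas_model`.
#' @param pair region-code pair.
#' @param p_thr probability threshold in `[0, 1]`; the recommended
#'   application setting is 0.3.
#' @return integer matrix of 0-based voxel indices (columns x, y, z).
#' @export
bundle_voxel_set <- function(a, pair, p_thr = 0.3) {
  stopifnot(inherits(a, "atlas_model"), p_thr >= 0, p_thr <= 1)
  sp <- .get_spam(a, pair)
  prob <- sp$voxels[, "count"] / sp$nsubjects
  sp$voxels[prob >= p_thr, 1:3, drop = FALSE]
}

# valid pairs under the consistency cut, as row indices into a$retained
.valid_pairs <- function(a, c_thr) {
  if (nrow(a$retained) == 0L) return(integer())
  S <- a$header$nsubjects
  codes <- a$matrices$codes
  min_cons <- .frac_to_count(c_thr, S)
  keep <- logical(nrow(a$retained))
  for (r in seq_len(nrow(a$retained))) {
    i <- match(a$retained[r, 1L], codes)
    j <- match(a$retained[r, 2L], codes)
    keep[r] <- a$matrices$consistency[i, j] >= min_cons
  }
  which(keep)
}

#' Scalar-weighted connectome
#'
#' For every atlas bundle passing the inter-subject consistency cut
#' (`consistency/S >= c_thr`) and having a non-empty thresholded voxel
#' set, computes the mean, median and standard deviation of the scalar
#' volume over those voxels. Connections failing either cut are flagged
#' invalid rather than set to 0 (0 is a legal scalar mean). The standard
#' deviation uses population normalization (divide by n).
#'
#' @param a an `atlas_model`.
#' @param values 3-D numeric array on the atlas grid.
#' @param p_thr voxel-wise probability threshold (default 0.3).
#' @param c_thr inter-subject consistency threshold as a fraction
#'   (default 0.30; mapped to `ceil(c_thr * S)` subjects).
#' @param scale scale identifier carried into the result.
#' @return an object of class `scalar_connectome` with N x N `mean`,
#'   `median`, `std` matrices, a logical `valid` mask, `codes` and the
#'   thresholds used.
#' @export
scalar_connectome <- function(a, values, p_thr = 0.3, c_thr = 0.30,
                              scale = NULL) {
  stopifnot(inherits(a, "atlas_model"))
  values <- as.array(values)
  .check_grid(a, values)
  if (is.null(scale)) scale <- a$header$scale
  codes <- a$matrices$codes
  n <- length(codes)
  mean_m <- med_m <- std_m <- matrix(NA_real_, n, n)
  valid <- matrix(FALSE, n, n)
  for (r in .valid_pairs(a, c_thr)) {
    pr <- a$retained[r, ]
    vox <- bundle_voxel_set(a, pr, p_thr)
    if (nrow(vox) == 0L) next
    x <- values[vox + 1L]
    i <- match(pr[1L], codes)
    j <- match(pr[2L], codes)
    mean_m[i, j] <- mean_m[j, i] <- mean(x)
    med_m[i, j] <- med_m[j, i] <- stats::median(x)
    std_m[i, j] <- std_m[j, i] <- sqrt(mean((x - mean(x))^2))
    valid[i, j] <- valid[j, i] <- TRUE
  }
  structure(list(mean = mean_m, median = med_m, std = std_m,
                 valid = valid, codes = codes, scale = scale,
                 p_thr = p_thr, c_thr = c_thr),
            class = "scalar_connectome")
}

#' @export
print.scalar_connectome <- function(x, ...) {
  cat("scalar_connectome:", length(x$codes), "regions,",
      sum(x$valid[upper.tri(x$valid)]), "valid connections (p_thr =",
      x$p_thr, ", c_thr =", x$c_thr, ")\n")
  invisible(x)
}

#' Bundles intersecting a binary mask
#'
#' Returns the region pairs whose thresholded voxel set intersects the
#' non-zero voxels of the mask, plus the union of their thresholded
#' supports as a binary volume.
#'
#' @param a an `atlas_model`.
#' @param mask binary array on the atlas grid.
#' @param p_thr probability threshold.
#' @return list with `pairs` (two-column code matrix) and `union_mask`
#'   (logical array).
#' @export
bundles_intersecting_mask <- function(a, mask, p_thr = 0.3) {
  stopifnot(inherits(a, "atlas_model"))
  mask <- as.array(mask) != 0
  .check_grid(a, mask)
  hit <- matrix(integer(), 0L, 2L)
  union_mask <- array(FALSE, a$header$dim)
  if (nrow(a$retained)) {
    for (r in seq_len(nrow(a$retained))) {
      pr <- a$retained[r, ]
      vox <- bundle_voxel_set(a, pr, p_thr)
      if (nrow(vox) == 0L) next
      if (any(mask[vox + 1L])) {
        hit <- rbind(hit, pr)
        union_mask[vox + 1L] <- TRUE
      }
    }
  }
  colnames(hit) <- c("i", "j")
  rownames(hit) <- NULL
  list(pairs = hit, union_mask = union_mask)
}

#' Bundles connecting two or more ROIs
#'
#' Returns the region pairs whose thresholded support intersects at least
#' two distinct labels of the ROI volume (support-intersection semantics).
#'
#' @param a an `atlas_model`.
#' @param rois a [label_volume()] or labeled integer array on the atlas
#'   grid.
#' @param p_thr probability threshold.
#' @return two-column code matrix of pairs.
#' @export
bundles_connecting_rois <- function(a, rois, p_thr = 0.3) {
  stopifnot(inherits(a, "atlas_model"))
  lab <- if (inherits(rois, "label_volume")) rois$labels else
    as.array(rois)
  .check_grid(a, lab)
  n_labels <- length(setdiff(unique(as.vector(lab)), 0L))
  hit <- matrix(integer(), 0L, 2L)
  colnames(hit) <- c("i", "j")
  if (n_labels < 2L) {
    message("fewer than two ROI labels supplied; no bundle can connect ",
            "two or more ROIs")
    return(hit)
  }
  for (r in seq_len(nrow(a$retained))) {
    pr <- a$retained[r, ]
    vox <- bundle_voxel_set(a, pr, p_thr)
    if (nrow(vox) == 0L) next
    touched <- setdiff(unique(lab[vox + 1L]), 0L)
    if (length(touched) >= 2L) hit <- rbind(hit, pr)
  }
  rownames(hit) <- NULL
  hit
}

#' Lesion impact ("dysconnectome") report
#'
#' For each valid bundle, the lesion load is the probability-weighted
#' fraction of the bundle's thresholded support covered by the lesion:
#' `load = sum(prob(v), v in support AND lesion) / sum(prob(v), v in
#' support)`. The unweighted voxel fraction is reported alongside. A
#' bundle is affected iff its load is positive. Per-region aggregates sum
#' the loads of incident bundles. If a scalar volume is supplied, the
#' bundle-wise mean/median/std of the scalar are appended.
#'
#' @param a an `atlas_model`.
#' @param lesion binary array on the atlas grid.
#' @param p_thr,c_thr thresholds as in [scalar_connectome()].
#' @param scalar optional 3-D scalar array on the atlas grid.
#' @return an object of class `lesion_report`: list with data frames
#'   `pairs` and `regions`.
#' @export
lesion_impact <- function(a, lesion, p_thr = 0.3, c_thr = 0.30,
                          scalar = NULL) {
  stopifnot(inherits(a, "atlas_model"))
  lesion <- as.array(lesion) != 0
  .check_grid(a, lesion)
  if (!is.null(scalar)) {
    scalar <- as.array(scalar)
    .check_grid(a, scalar)
  }
  reg <- a$header$regions
  rows <- list()
  for (r in .valid_pairs(a, c_thr)) {
    pr <- a$retained[r, ]
    sp <- .get_spam(a, pr)
    prob <- sp$voxels[, "count"] / sp$nsubjects
    keep <- prob >= p_thr
    if (!any(keep)) next
    vox <- sp$voxels[keep, 1:3, drop = FALSE]
    p <- prob[keep]
    inles <- lesion[vox + 1L]
    load <- sum(p[inles]) / sum(p)
    vfrac <- mean(inles)
    row <- data.frame(i = pr[1L], j = pr[2L],
                      name_i = reg$name[match(pr[1L], reg$code)],
                      name_j = reg$name[match(pr[2L], reg$code)],
                      load = load, voxel_fraction = vfrac,
                      affected = load > 0,
                      stringsAsFactors = FALSE)
    if (!is.null(scalar)) {
      x <- scalar[vox + 1L]
      row$mean <- mean(x)
      row$median <- stats::median(x)
      row$std <- sqrt(mean((x - mean(x))^2))
    }
    rows[[length(rows) + 1L]] <- row
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), name_i = character(),
               name_j = character(), load = numeric(),
               voxel_fraction = numeric(), affected = logical())
  agg <- numeric(nrow(reg))
  for (k in seq_len(nrow(pairs))) {
    agg[match(pairs$i[k], reg$code)] <-
      agg[match(pairs$i[k], reg$code)] + pairs$load[k]
    agg[match(pairs$j[k], reg$code)] <-
      agg[match(pairs$j[k], reg$code)] + pairs$load[k]
  }
  regions <- data.frame(code = reg$code, name = reg$name, load = agg,
                        stringsAsFactors = FALSE)
  structure(list(pairs = pairs, regions = regions,
                 p_thr = p_thr, c_thr = c_thr),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat("lesion_report:", nrow(x$pairs), "bundles evaluated,",
      sum(x$pairs$affected), "affected\n")
  invisible(x)
}

#' Whole-brain connectivity density
#'
#' Percentage of all possible region pairs covered by bundles:
#' `100 * n_bundle / (n_gm * (n_gm - 1) / 2)`.
#'
#' @param n_gm number of gray-matter regions (>= 2).
#' @param n_bundle number of bundles.
#' @return density in percent.
#' @export
connectivity_density <- function(n_gm, n_bundle) {
  if (any(n_gm < 2)) stop("density requires at least 2 regions")
  100 * n_bundle / (n_gm * (n_gm - 1) / 2)
}

#' Atlas density summary
#'
#' @param a an `atlas_model`.
#' @return one-row data frame with `scale`, `n_regions`, `n_bundles` and
#'   `density` (percent).
#' @export
atlas_density_summary <- function(a) {
  stopifnot(inherits(a, "atlas_model"))
  ng <- nrow(a$header$regions)
  if (ng < 2L) stop("density requires at least 2 regions")
  data.frame(scale = if (is.null(a$header$scale)) NA_integer_ else
               a$header$scale,
             n_regions = ng, n_bundles = n_bundles(a),
             density = connectivity_density(ng, n_bundles(a)))
}

#' Region bookkeeping of the four-scale parcellation
#'
#' The multi-scale gray-matter scheme combines a cortical parcellation
#' (68, 114, 216 and 446 regions at scales 1-4, scale 1 being the
#' Desikan-Killiany atlas) with a fixed subcortical complement: six
#' bilateral structures (caudate, putamen, accumbens, pallidum, amygdala,
#' hippocampus), seven thalamic nuclei per hemisphere, and the brainstem.
#'
#' @param cortical number of cortical regions.
#' @return total region count: `cortical + 2*6 + 2*7 + 1`.
#' @export
parcellation_region_count <- function(cortical) {
  cortical + 2L * 6L + 2L * 7L + 1L
}

#' @rdname parcellation_region_count
#' @return `multiscale_region_table()`: data frame with one row per scale
#'   (`scale`, `cortical`, `total`).
#' @export
multiscale_region_table <- function() {
  cortical <- c(68L, 114L, 216L, 446L)
  data.frame(scale = 1:4, cortical = cortical,
             total = parcellation_region_count(cortical))
}
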