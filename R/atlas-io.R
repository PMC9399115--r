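#' Atlas file format
#'
#' The atlas is serialized as a single HDF5 file with three groups:
#'
#' * `header/` -- `nsubjects`, `dim`, `voxsize`, `affine`, and the
#'   gray-matter region arrays `gmregions` (names), `gmcodes`,
#'   `gmcolors` (N x 3 RGB) and `gmcoords` (N x 3 centroid mm).
#' * `matrices/` -- `consistency` (integer subject counts),
#'   `numbStlines` (mean NOS) and `length` (mean mm), each N x N.
#' * `atlas/` -- one dataset per bundle named `"a_b"` after the two region
#'   codes it connects (e.g. `1_10`), an N_ab x 4 integer matrix whose
#'   rows are 0-based voxel x, y, z indices plus the subject-consistency
#'   count of the voxel.
#'
#' @name atlas-io
NULL

#' Write an atlas to HDF5
#'
#' @param a an `atlas_model`.
#' @param path output `.h5` path (overwritten if present).
#' @return the path, invisibly.
#' @export
write_atlas_h5 <- function(a, path) {
  stopifnot(inherits(a, "atlas_model"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (grp in c("header", "matrices", "atlas"))
    rhdf5::h5createGroup(path, grp)
  h <- a$header
  rhdf5::h5write(as.integer(h$nsubjects), path, "header/nsubjects")
  rhdf5::h5write(as.integer(h$dim), path, "header/dim")
  rhdf5::h5write(as.numeric(h$voxsize), path, "header/voxsize")
  rhdf5::h5write(as.matrix(h$affine), path, "header/affine")
  rhdf5::h5write(as.character(h$regions$name), path, "header/gmregions")
  rhdf5::h5write(as.integer(h$regions$code), path, "header/gmcodes")
  colors <- as.matrix(h$regions[, c("R", "G", "B")])
  storage.mode(colors) <- "integer"
  dimnames(colors) <- NULL
  rhdf5::h5write(colors, path, "header/gmcolors")
  coords <- as.matrix(h$regions[, c("x", "y", "z")])
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  rhdf5::h5write(coords, path, "header/gmcoords")
  cons <- a$matrices$consistency
  storage.mode(cons) <- "integer"
  rhdf5::h5write(cons, path, "matrices/consistency")
  rhdf5::h5write(unname(a$matrices$numbStlines), path,
                 "matrices/numbStlines")
  rhdf5::h5write(unname(a$matrices$length), path, "matrices/length")
  for (key in names(a$spams)) {
    vox <- a$spams[[key]]$voxels
    dimnames(vox) <- NULL
    storage.mode(vox) <- "integer"
    rhdf5::h5write(vox, path, paste0("atlas/", key))
  }
  invisible(path)
}

#' Read an atlas from HDF5
#'
#' Validates the layout (three groups, complete header, N x 4 bundle
#' datasets, voxel counts within 1..nsubjects) and reconstructs a full
#' `atlas_model`; no partial model is returned on malformed input.
#' Region hemispheres are not stored in the file and are inferred from the
#' leading character of the region name (`L`/`R`, otherwise `M`).
#'
#' @param path input `.h5` path.
#' @param index_base base of the stored voxel indices (0 by default;
#'   pass 1 for files written with 1-based indices).
#' @return an `atlas_model`.
#' @export
read_atlas_h5 <- function(path, index_base = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- tryCatch(rhdf5::h5ls(path),
                 error = function(e)
                   stop("format error: not a readable HDF5 atlas: ", path))
  top <- ls$name[ls$group == "/"]
  for (grp in c("header", "matrices", "atlas"))
    if (!grp %in% top)
      stop("format error: missing group '", grp, "' in ", path)
  hdr_sets <- ls$name[ls$group == "/header"]
  needed <- c("nsubjects", "dim", "voxsize", "affine", "gmregions",
              "gmcodes", "gmcolors", "gmcoords")
  miss <- setdiff(needed, hdr_sets)
  if (length(miss))
    stop("format error: missing header dataset(s): ",
         paste0("header/", miss, collapse = ", "))
  mat_sets <- ls$name[ls$group == "/matrices"]
  miss <- setdiff(c("consistency", "numbStlines", "length"), mat_sets)
  if (length(miss))
    stop("format error: missing matrices dataset(s): ",
         paste0("matrices/", miss, collapse = ", "))
  rd <- function(name) rhdf5::h5read(path, name)
  S <- as.integer(rd("header/nsubjects"))
  dm <- as.integer(rd("header/dim"))
  vs <- as.numeric(rd("header/voxsize"))
  aff <- as.matrix(rd("header/affine"))
  names_ <- as.character(rd("header/gmregions"))
  codes <- as.integer(rd("header/gmcodes"))
  colors <- as.matrix(rd("header/gmcolors"))
  coords <- as.matrix(rd("header/gmcoords"))
  ng <- length(codes)
  if (length(names_) != ng || nrow(colors) != ng || nrow(coords) != ng)
    stop("format error: header GM arrays have inconsistent lengths")
  first <- substr(names_, 1L, 1L)
  hemi <- ifelse(first %in% c("L", "R"), first, "M")
  regions <- data.frame(code = codes, name = names_, hemisphere = hemi,
                        R = colors[, 1L], G = colors[, 2L], B = colors[, 3L],
                        x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
                        stringsAsFactors = FALSE)
  cons <- as.matrix(rd("matrices/consistency"))
  storage.mode(cons) <- "integer"
  nosm <- as.matrix(rd("matrices/numbStlines"))
  lenm <- as.matrix(rd("matrices/length"))
  if (!all(dim(cons) == ng) || !all(dim(nosm) == ng) ||
      !all(dim(lenm) == ng))
    stop("format error: matrices are not N_GM x N_GM")
  group <- structure(list(consistency = cons, numbStlines = nosm,
                          length = lenm, nsubjects = S, codes = codes),
                     class = "group_matrices")
  keys <- ls$name[ls$group == "/atlas"]
  spams <- list()
  pairs <- matrix(integer(), 0L, 2L)
  for (key in keys) {
    dat <- rd(paste0("atlas/", key))
    dat <- as.matrix(dat)
    if (ncol(dat) != 4L)
      stop("format error: dataset atlas/", key, " is not N x 4")
    storage.mode(dat) <- "integer"
    dat[, 1:3] <- dat[, 1:3] - as.integer(index_base)
    if (any(dat[, 4L] < 1L))
      stop("corruption error: dataset atlas/", key,
           " has voxel counts below 1")
    if (any(dat[, 4L] > S))
      stop("corruption error: dataset atlas/", key,
           " has voxel counts above nsubjects")
    colnames(dat) <- c("x", "y", "z", "count")
    ij <- sort(as.integer(strsplit(key, "_", fixed = TRUE)[[1L]]))
    ckey <- pair_key(ij[1L], ij[2L])
    spams[[ckey]] <- structure(list(pair = ij, voxels = dat,
                                    nsubjects = S, dim = dm,
                                    affine = aff),
                               class = "spam")
    pairs <- rbind(pairs, ij)
  }
  if (nrow(pairs)) {
    ord <- order(pairs[, 1L], pairs[, 2L])
    pairs <- pairs[ord, , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  rownames(pairs) <- NULL
  header <- list(nsubjects = S, dim = dm, voxsize = vs, affine = aff,
                 regions = regions)
  assemble_atlas(header, group, spams, pairs)
}

.get_spam <- function(a, pair) {
  key <- pair_key(pair[1L], pair[2L])
  sp <- a$spams[[key]]
  if (is.null(sp)) {
    near <- grep(paste0("(^", pair[1L], "_|_", pair[1L], "$|^", pair[2L],
                        "_|_", pair[2L], "$)"), names(a$spams), value = TRUE)
    stop("no bundle ", key, " in the atlas",
         if (length(near)) paste0("; bundles touching these regions: ",
                                  paste(utils::head(near, 10L),
                                        collapse = ", ")))
  }
  sp
}

#' Export a bundle's probability volume
#'
#' Dense 3-D grid holding count/S at the bundle's stored voxels whose
#' probability is at least `p_thr`, and 0 elsewhere.
#'
#' @param a an `atlas_model`.
#' @param pair region-code pair.
#' @param p_thr probability threshold in `[0, 1]` (inclusive).
#' @return numeric array of probabilities.
#' @export
export_bundle_probability_volume <- function(a, pair, p_thr = 0) {
  stopifnot(inherits(a, "atlas_model"), p_thr >= 0, p_thr <= 1)
  sp <- .get_spam(a, pair)
  vol <- array(0, a$header$dim)
  prob <- sp$voxels[, "count"] / sp$nsubjects
  keep <- prob >= p_thr
  if (any(keep))
    vol[sp$voxels[keep, 1:3, drop = FALSE] + 1L] <- prob[keep]
  vol
}

#' Export a color-coded bundle volume
#'
#' 4-D array `[dim, 3]` in which each voxel's RGB color is the
#' probability-weighted average of the colors of the bundles traversing
#' it; a bundle's color is the mean of its two endpoint-region colors.
#' Voxels traversed by no bundle are 0.
#'
#' @param a an `atlas_model`.
#' @param p_thr probability threshold in `[0, 1]`.
#' @return numeric 4-D array (last dimension = R, G, B).
#' @export
export_color_coded_volume <- function(a, p_thr = 0) {
  stopifnot(inherits(a, "atlas_model"))
  dm <- a$header$dim
  nvox <- prod(dm)
  num <- matrix(0, nvox, 3L)
  den <- numeric(nvox)
  reg <- a$header$regions
  for (key in names(a$spams)) {
    sp <- a$spams[[key]]
    prob <- sp$voxels[, "count"] / sp$nsubjects
    keep <- prob >= p_thr
    if (!any(keep)) next
    v <- sp$voxels[keep, 1:3, drop = FALSE]
    lin <- v[, 1L] + dm[1L] * (v[, 2L] + dm[2L] * v[, 3L]) + 1L
    ij <- sp$pair
    col <- colMeans(as.matrix(
      reg[match(ij, reg$code), c("R", "G", "B")]))
    p <- prob[keep]
    for (c in 1:3) {
      upd <- tapply(p * col[c], lin, sum)
      idx <- as.integer(names(upd))
      num[idx, c] <- num[idx, c] + as.numeric(upd)
    }
    updd <- tapply(p, lin, sum)
    idxd <- as.integer(names(updd))
    den[idxd] <- den[idxd] + as.numeric(updd)
  }
  out <- array(0, c(dm, 3L))
  nz <- den > 0
  if (any(nz)) {
    scaled <- num[nz, , drop = FALSE] / den[nz]
    for (c in 1:3) {
      plane <- numeric(nvox)
      plane[nz] <- scaled[, c]
      out[, , , c] <- array(plane, dm)
    }
  }
  out
}

#' Export the per-voxel bundle count volume
#'
#' Counts, per voxel, the number of distinct atlas bundles whose
#' thresholded support contains the voxel.
#'
#' @param a an `atlas_model`.
#' @param p_thr probability threshold in `[0, 1]`.
#' @return integer array.
#' @export
export_bundle_count_volume <- function(a, p_thr = 0) {
  stopifnot(inherits(a, "atlas_model"))
  dm <- a$header$dim
  counts <- array(0L, dm)
  for (key in names(a$spams)) {
    sp <- a$spams[[key]]
    prob <- sp$voxels[, "count"] / sp$nsubjects
    keep <- prob >= p_thr
    if (!any(keep)) next
    idx <- sp$voxels[keep, 1:3, drop = FALSE] + 1L
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

#' Export the three atlas matrices as CSV
#'
#' @param a an `atlas_model`.
#' @param prefix path prefix; writes `<prefix>_consistency.csv`,
#'   `<prefix>_numbStlines.csv`, `<prefix>_length.csv`.
#' @return the paths, invisibly.
#' @export
write_atlas_matrices_csv <- function(a, prefix) {
  stopifnot(inherits(a, "atlas_model"))
  paths <- character(3L)
  mats <- list(consistency = a$matrices$consistency,
               numbStlines = a$matrices$numbStlines,
               length = a$matrices$length)
  for (k in seq_along(mats)) {
    paths[k] <- paste0(prefix, "_", names(mats)[k], ".csv")
    write_matrix_csv(mats[[k]], a$matrices$codes, paths[k])
  }
  invisible(paths)
}
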