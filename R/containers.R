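#' Core containers and grid bookkeeping
#'
#' Conventions used throughout the package: coordinates are world mm (RAS);
#' voxel indices are 0-based integers; a grid affine maps 0-based voxel
#' indices to the world coordinate of the voxel center, matching the
#' NIfTI-1 convention.
#'
#' @name containers
NULL

# voxel sizes (mm) implied by an affine
.affine_voxsize <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# world (n x 3) -> continuous 0-based voxel coordinates (n x 3)
.world_to_voxel <- function(affine, pts) {
  inv <- solve(affine)
  .apply_affine(inv, as.matrix(pts))
}

# world (n x 3) -> integer 0-based voxel indices (nearest voxel center)
.voxel_of <- function(affine, pts) {
  v <- round(.world_to_voxel(affine, pts))
  storage.mode(v) <- "integer"
  v
}

# 0-based voxel indices (n x 3) -> world coordinates of voxel centers
.voxel_to_world <- function(affine, vox) {
  .apply_affine(affine, as.matrix(vox))
}

.in_grid <- function(vox, dim) {
  vox[, 1L] >= 0L & vox[, 1L] < dim[1L] &
    vox[, 2L] >= 0L & vox[, 2L] < dim[2L] &
    vox[, 3L] >= 0L & vox[, 3L] < dim[3L]
}

# canonical "i_j" key for an unordered region pair
pair_key <- function(i, j) {
  paste0(pmin(i, j), "_", pmax(i, j))
}

.parse_pair_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)
  t(vapply(parts, function(p) sort(as.integer(p)), integer(2L)))
}

#' Tractogram container
#'
#' A set of streamlines together with the acquisition grid they were
#' reconstructed on (voxel-to-world affine, grid dimensions and voxel
#' sizes).
#'
#' @param streamlines list of n x 3 streamline matrices (world mm).
#' @param affine invertible 4 x 4 voxel-to-world matrix.
#' @param dim 3 positive integers.
#' @param voxsize 3 positive voxel edge lengths in mm; defaults to the
#'   sizes implied by `affine`.
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines, affine = diag(4), dim,
                       voxsize = NULL) {
  affine <- as.matrix(affine)
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim <= 0L))
    stop("dim must be 3 positive integers")
  if (is.null(voxsize)) voxsize <- .affine_voxsize(affine)
  if (any(voxsize <= 0)) stop("voxsize must be positive")
  streamlines <- lapply(streamlines, as_streamline)
  structure(list(streamlines = streamlines, affine = affine,
                 dim = dim, voxsize = as.numeric(voxsize)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat("tractogram:", length(x$streamlines), "streamlines on a",
      paste(x$dim, collapse = " x "), "grid (voxel",
      paste(signif(x$voxsize, 3), collapse = " x "), "mm)\n")
  invisible(x)
}

#' Labeled parcellation volume
#'
#' A 3-D integer label grid plus a region table. Label 0 is background;
#' every non-zero label in the grid must appear in the table, and codes are
#' unique.
#'
#' @param labels 3-D integer array.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param table data frame with columns `code` (integer > 0), `name`,
#'   `hemisphere` (one of "L", "R", "M"), `R`, `G`, `B` (0-255) and
#'   centroid columns `x`, `y`, `z` (mm).
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, affine, table) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  needed <- c("code", "name", "hemisphere", "R", "G", "B", "x", "y", "z")
  if (!all(needed %in% names(table)))
    stop("label table must have columns: ", paste(needed, collapse = ", "))
  table$code <- as.integer(table$code)
  if (anyDuplicated(table$code)) stop("label codes must be unique")
  if (any(table$code <= 0L)) stop("label codes must be positive")
  if (!all(table$hemisphere %in% c("L", "R", "M")))
    stop("hemisphere must be one of L, R, M")
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(present %in% table$code))
    stop("grid contains labels missing from the table: ",
         paste(setdiff(present, table$code), collapse = ", "))
  structure(list(labels = labels, affine = as.matrix(affine),
                 table = as.data.frame(table, stringsAsFactors = FALSE)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", nrow(x$table), "regions on a",
      paste(dim(x$labels), collapse = " x "), "grid\n")
  invisible(x)
}

#' Subject-level connectivity matrices
#'
#' Number-of-streamlines (NOS) and mean-length matrices for one subject,
#' indexed by region code. Both are symmetric with zero diagonal, and the
#' length is 0 wherever the NOS is 0.
#'
#' @param nos,length square numeric matrices.
#' @param codes integer region codes labeling rows/columns.
#' @return an object of class `subject_connectome`.
#' @export
subject_connectome <- function(nos, length, codes) {
  nos <- as.matrix(nos); length <- as.matrix(length)
  codes <- as.integer(codes)
  n <- base::length(codes)
  stopifnot(all(dim(nos) == n), all(dim(length) == n))
  if (any(nos < 0) || any(length < 0))
    stop("nos and length must be non-negative")
  if (any(abs(nos - t(nos)) > 0) || any(abs(length - t(length)) > 1e-9))
    stop("matrices must be symmetric")
  if (any(diag(nos) != 0) || any(diag(length) != 0))
    stop("diagonals must be zero")
  if (any(length[nos == 0] != 0))
    stop("length must be 0 where nos is 0")
  dimnames(nos) <- dimnames(length) <- list(codes, codes)
  structure(list(nos = nos, length = length, codes = codes),
            class = "subject_connectome")
}

#' @export
print.subject_connectome <- function(x, ...) {
  cat("subject_connectome:", length(x$codes), "regions,",
      sum(x$nos[upper.tri(x$nos)] > 0), "connections,",
      sum(x$nos) / 2, "streamlines\n")
  invisible(x)
}

#' Write a 3-D or 4-D volume as NIfTI-1
#'
#' @param values numeric array.
#' @param affine 4 x 4 voxel-to-world matrix (0-based indices).
#' @param path output file (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(values, affine, path) {
  img <- RNifti::asNifti(values)
  RNifti::sform(img) <- structure(as.matrix(affine), code = 2L)
  RNifti::qform(img) <- structure(as.matrix(affine), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path input file.
#' @return list with `values` (array) and `affine` (4 x 4).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = as.array(img), affine = unclass(RNifti::xform(img)))
}
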