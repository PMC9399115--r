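#' Plain-text tractogram container
#'
#' Tractograms are exchanged in a simple columnar text format: header
#' comment lines carrying the grid metadata, then one point per row with a
#' streamline index column.
#'
#' ```
#' # tractogram v1
#' # affine: <16 numbers, row-major>
#' # dim: <3 integers>
#' # voxsize: <3 numbers>
#' streamline<TAB>x<TAB>y<TAB>z
#' 1<TAB>...
#' ```
#'
#' @param t a [tractogram()].
#' @param path output path (`.tsv`).
#' @return the path, invisibly.
#' @export
write_tractogram_tsv <- function(t, path) {
  stopifnot(inherits(t, "tractogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# tractogram v1",
    paste("# affine:", paste(format(t(t$affine), digits = 17),
                             collapse = " ")),
    paste("# dim:", paste(t$dim, collapse = " ")),
    paste("# voxsize:", paste(format(t$voxsize, digits = 17),
                              collapse = " "))
  ), con)
  n_pts <- vapply(t$streamlines, nrow, integer(1L))
  if (sum(n_pts) > 0) {
    tab <- data.frame(
      streamline = rep(seq_along(t$streamlines), n_pts),
      do.call(rbind, t$streamlines)
    )
    names(tab) <- c("streamline", "x", "y", "z")
  } else {
    tab <- data.frame(streamline = integer(), x = numeric(),
                      y = numeric(), z = numeric())
  }
  suppressWarnings(utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                                      quote = FALSE))
  invisible(path)
}

#' @rdname write_tractogram_tsv
#' @export
read_tractogram_tsv <- function(path) {
  lines <- readLines(path, n = 4L)
  if (length(lines) < 4L || !startsWith(lines[1L], "# tractogram"))
    stop("not a tractogram TSV file: ", path)
  grab <- function(prefix, i) {
    if (!startsWith(lines[i], prefix))
      stop("malformed tractogram header (expected '", prefix, "')")
    as.numeric(strsplit(trimws(sub(prefix, "", lines[i], fixed = TRUE)),
                        "\\s+")[[1L]])
  }
  affine <- matrix(grab("# affine:", 2L), 4L, 4L, byrow = TRUE)
  dm <- as.integer(grab("# dim:", 3L))
  vs <- grab("# voxsize:", 4L)
  tab <- utils::read.delim(path, comment.char = "#")
  if (nrow(tab) == 0) {
    sls <- list()
  } else {
    sls <- lapply(split(seq_len(nrow(tab)), tab$streamline),
                  function(idx) as.matrix(tab[idx, c("x", "y", "z")]))
    sls <- sls[order(as.integer(names(sls)))]
    names(sls) <- NULL
  }
  tractogram(sls, affine = affine, dim = dm, voxsize = vs)
}

#' Read and write labeled parcellations
#'
#' The label grid travels as a NIfTI-1 integer volume and the region table
#' as a CSV with columns `code,name,hemisphere,R,G,B,x,y,z`.
#'
#' @param p a [label_volume()].
#' @param nii_path NIfTI path for the label grid.
#' @param csv_path CSV path for the region table.
#' @return the paths, invisibly.
#' @export
write_label_volume <- function(p, nii_path, csv_path) {
  stopifnot(inherits(p, "label_volume"))
  write_nifti_volume(p$labels, p$affine, nii_path)
  utils::write.csv(p$table, csv_path, row.names = FALSE)
  invisible(c(nii_path, csv_path))
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(nii_path, csv_path) {
  vol <- read_nifti_volume(nii_path)
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  label_volume(round(vol$values), vol$affine, tab)
}

#' Export a square matrix as CSV with region-code headers
#'
#' @param m square matrix indexed by region code.
#' @param codes integer region codes.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_matrix_csv <- function(m, codes, path) {
  m <- as.matrix(m)
  dimnames(m) <- list(codes, codes)
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  colnames(m) <- colnames(tab)
  m
}
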