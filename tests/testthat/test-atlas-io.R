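# minimal hand-built atlas: regions 1 (red) and 10 (blue), one bundle of
# two voxels on a 6^3 grid, 4 subjects
toy_atlas <- function(second_pair = FALSE) {
  dm <- c(6L, 6L, 6L)
  regions <- data.frame(code = c(1L, 10L, 11L),
                        name = c("L1", "R1", "R2"),
                        hemisphere = c("L", "R", "R"),
                        R = c(255, 0, 0), G = c(0, 0, 0),
                        B = c(0, 255, 255),
                        x = c(1, 4, 4), y = c(1, 1, 4), z = c(1, 1, 1))
  n <- 3L
  nos <- matrix(0, n, n); lens <- matrix(0, n, n)
  nos[1, 2] <- nos[2, 1] <- 2; lens[1, 2] <- lens[2, 1] <- 25
  if (second_pair) { nos[1, 3] <- nos[3, 1] <- 1
                     lens[1, 3] <- lens[3, 1] <- 30 }
  sc <- subject_connectome(nos, lens, regions$code)
  group <- group_connectivity(rep(list(sc), 4))
  spams <- list(
    "1_10" = spam(c(1L, 10L), rbind(c(2, 2, 2, 3), c(3, 2, 2, 4)),
                  nsubjects = 4, dim = dm, affine = diag(4)))
  retained <- rbind(c(1L, 10L))
  if (second_pair) {
    spams[["1_11"]] <- spam(c(1L, 11L),
                            rbind(c(3, 2, 2, 4), c(3, 3, 2, 2)),
                            nsubjects = 4, dim = dm, affine = diag(4))
    retained <- rbind(retained, c(1L, 11L))
  }
  header <- list(nsubjects = 4L, dim = dm, voxsize = c(1, 1, 1),
                 affine = diag(4), regions = regions, scale = 1L)
  assemble_atlas(header, group, spams, retained)
}

test_that("HDF5 layout: naming, shapes, and exact round trips", {
  a <- toy_atlas()
  f <- withr::local_tempfile(fileext = ".h5")
  write_atlas_h5(a, f)

  ls <- rhdf5::h5ls(f)
  expect_setequal(ls$name[ls$group == "/"],
                  c("header", "matrices", "atlas"))
  # the bundle between regions 1 and 10 is stored as dataset "1_10"
  expect_identical(ls$name[ls$group == "/atlas"], "1_10")
  expect_identical(ls$dim[ls$group == "/atlas"], "2 x 4")

  a2 <- read_atlas_h5(f)
  expect_equal(a2$header$nsubjects, a$header$nsubjects)
  expect_equal(a2$header$dim, a$header$dim)
  expect_equal(a2$header$affine, unname(a$header$affine))
  expect_identical(unname(a2$matrices$consistency),
                   unname(a$matrices$consistency))
  expect_equal(unname(a2$matrices$numbStlines),
               unname(a$matrices$numbStlines))
  expect_equal(unname(a2$matrices$length), unname(a$matrices$length))
  expect_identical(a2$spams[["1_10"]]$voxels, a$spams[["1_10"]]$voxels)
  expect_identical(unname(a2$retained), unname(a$retained))
  expect_identical(a2$header$regions$hemisphere,
                   a$header$regions$hemisphere)

  # write -> read -> write: datasets byte-identical between the files
  f2 <- withr::local_tempfile(fileext = ".h5")
  write_atlas_h5(a2, f2)
  for (ds in c("header/nsubjects", "header/dim", "header/gmcodes",
               "matrices/consistency", "matrices/numbStlines",
               "matrices/length", "atlas/1_10")) {
    expect_identical(rhdf5::h5read(f, ds), rhdf5::h5read(f2, ds))
  }
})

test_that("phantom-built atlases survive the HDF5 round trip", {
  res <- phantom5()
  f <- withr::local_tempfile(fileext = ".h5")
  write_atlas_h5(res$atlas, f)
  a2 <- read_atlas_h5(f)
  expect_equal(n_bundles(a2), n_bundles(res$atlas))
  for (key in names(res$atlas$spams))
    expect_identical(a2$spams[[key]]$voxels, res$atlas$spams[[key]]$voxels)
  expect_identical(unname(a2$retained), unname(res$atlas$retained))
})

test_that("malformed files are rejected with diagnostics, never partially read", {
  a <- toy_atlas()
  f <- withr::local_tempfile(fileext = ".h5")
  write_atlas_h5(a, f)

  # truncation destroys the file wholesale
  raw <- readBin(f, "raw", file.info(f)$size)
  f_trunc <- withr::local_tempfile(fileext = ".h5")
  writeBin(raw[seq_len(200)], f_trunc)
  expect_error(read_atlas_h5(f_trunc), "format error")

  # a missing group is named in the diagnostic
  f_nogrp <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f_nogrp)
  rhdf5::h5createGroup(f_nogrp, "header")
  rhdf5::h5closeAll()
  expect_error(read_atlas_h5(f_nogrp), "matrices")

  # voxel counts above nsubjects are corruption
  bad <- a
  bad$spams[["1_10"]]$voxels[1, "count"] <- 9L
  f_bad <- withr::local_tempfile(fileext = ".h5")
  # bypass the constructor checks to simulate on-disk corruption
  rhdf5::h5createFile(f_bad)
  for (grp in c("header", "matrices", "atlas"))
    rhdf5::h5createGroup(f_bad, grp)
  h <- a$header
  rhdf5::h5write(h$nsubjects, f_bad, "header/nsubjects")
  rhdf5::h5write(h$dim, f_bad, "header/dim")
  rhdf5::h5write(h$voxsize, f_bad, "header/voxsize")
  rhdf5::h5write(h$affine, f_bad, "header/affine")
  rhdf5::h5write(h$regions$name, f_bad, "header/gmregions")
  rhdf5::h5write(h$regions$code, f_bad, "header/gmcodes")
  rhdf5::h5write(as.matrix(h$regions[, c("R", "G", "B")]), f_bad,
                 "header/gmcolors")
  rhdf5::h5write(as.matrix(h$regions[, c("x", "y", "z")]), f_bad,
                 "header/gmcoords")
  rhdf5::h5write(a$matrices$consistency, f_bad, "matrices/consistency")
  rhdf5::h5write(a$matrices$numbStlines, f_bad, "matrices/numbStlines")
  rhdf5::h5write(a$matrices$length, f_bad, "matrices/length")
  rhdf5::h5write(unname(bad$spams[["1_10"]]$voxels), f_bad, "atlas/1_10")
  rhdf5::h5closeAll()
  expect_error(read_atlas_h5(f_bad), "corruption")
})

test_that("probability volumes honor the threshold and the count/S scale", {
  a <- toy_atlas()
  # S = 4, counts 3 and 4: probabilities 0.75 and 1.0
  v0 <- export_bundle_probability_volume(a, c(1, 10), p_thr = 0)
  expect_equal(sum(v0 > 0), 2)
  expect_equal(v0[3, 3, 3], 0.75)
  expect_equal(v0[4, 3, 3], 1.0)

  expect_equal(sum(export_bundle_probability_volume(a, c(1, 10), 0.76) > 0),
               1)

  # p_thr just above the maximum probability empties the volume
  a_low <- toy_atlas()
  a_low$spams[["1_10"]]$voxels[, "count"] <- c(3L, 2L)
  v_zero <- export_bundle_probability_volume(a_low, c(1, 10), p_thr = 0.8)
  expect_true(all(v_zero == 0))

  expect_error(export_bundle_probability_volume(a, c(2, 5)), "no bundle")
})

test_that("color-coded exports average bundle colors by probability", {
  a1 <- toy_atlas()
  col <- export_color_coded_volume(a1)
  # a single bundle with one red endpoint and one blue endpoint gets the
  # mean color (127.5, 0, 127.5) along its whole support
  expect_equal(col[3, 3, 3, ], c(127.5, 0, 127.5))
  expect_equal(col[4, 3, 3, ], c(127.5, 0, 127.5))
  expect_equal(sum(col != 0), 4)

  # overlap voxel: probability-weighted average, verified by brute force
  a2 <- toy_atlas(second_pair = TRUE)
  col2 <- export_color_coded_volume(a2)
  p1 <- 4 / 4; p2 <- 4 / 4   # both bundles have count 4 at (3,2,2)
  c1 <- c(127.5, 0, 127.5); c2 <- c(127.5, 0, 127.5)
  expect_equal(col2[4, 3, 3, ], (p1 * c1 + p2 * c2) / (p1 + p2))
  # brute-force accumulation over every voxel
  dm <- a2$header$dim
  num <- array(0, c(dm, 3)); den <- array(0, dm)
  for (key in names(a2$spams)) {
    sp <- a2$spams[[key]]
    cols <- colMeans(as.matrix(
      a2$header$regions[match(sp$pair, a2$header$regions$code),
                        c("R", "G", "B")]))
    for (r in seq_len(nrow(sp$voxels))) {
      v <- sp$voxels[r, 1:3] + 1L
      p <- sp$voxels[r, "count"] / sp$nsubjects
      for (cc in 1:3)
        num[v[1], v[2], v[3], cc] <- num[v[1], v[2], v[3], cc] + p * cols[cc]
      den[v[1], v[2], v[3]] <- den[v[1], v[2], v[3]] + p
    }
  }
  expected <- array(0, c(dm, 3))
  for (cc in 1:3)
    expected[, , , cc] <- ifelse(den > 0, num[, , , cc] / den, 0)
  expect_equal(col2, expected)
})
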