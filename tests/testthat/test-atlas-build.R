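# hand-built 3-subject connectome set on four left-hemisphere regions;
# per-pair NOS by subject and a fixed per-pair length
hand_connectomes <- function() {
  codes <- 1:4
  lens <- rbind(c(0, 30, 50, 70), c(30, 0, 40, 60), c(50, 40, 0, 80),
                c(70, 60, 80, 0))
  nos_by_subject <- list(
    rbind(c(0, 2, 1, 0), c(2, 0, 3, 1), c(1, 3, 0, 1), c(0, 1, 1, 0)),
    rbind(c(0, 1, 0, 1), c(1, 0, 2, 1), c(0, 2, 0, 0), c(1, 1, 0, 0)),
    rbind(c(0, 3, 1, 0), c(3, 0, 1, 0), c(1, 1, 0, 1), c(0, 0, 1, 0)))
  lapply(nos_by_subject, function(nos)
    subject_connectome(nos, lens * (nos > 0), codes))
}

hand_regions <- function(hemi = rep("L", 4)) {
  data.frame(code = 1:4, name = paste0(hemi, 1:4), hemisphere = hemi,
             R = 200, G = 100, B = 50, x = 0, y = 0, z = 0)
}

test_that("TDI equals an exact independent segment-cube traversal oracle", {
  dm <- c(48L, 48L, 48L)
  # axis-aligned streamline through 7 voxel centers
  line <- cbind(seq(10, 16), 20, 20)
  tdi <- compute_tdi(list(line), dm, diag(4))
  expect_equal(sum(tdi$counts), 7)
  expect_true(all(tdi$counts[cbind(11:17, 21, 21)] == 1))

  # two identical streamlines double the counts on the same support
  tdi2 <- compute_tdi(list(line, line), dm, diag(4))
  expect_identical(tdi2$counts, tdi$counts * 2L)

  # random curved bundles against the brute-force slab oracle
  set.seed(19)
  for (k in 1:4) {
    p0 <- runif(3, 8, 14); p2 <- runif(3, 30, 40)
    arc <- bezier_arc(p0, p2, apex = rnorm(3, 0, 5))
    tdi <- compute_tdi(list(arc), dm, diag(4))
    got <- sort_voxels(which(tdi$counts > 0, arr.ind = TRUE) - 1L)
    expect_identical(got, unname(slab_traversal_oracle(arc, dm)))
  }

  # out-of-grid samples are dropped with a warning
  out <- rbind(c(-10, 5, 5), c(5, 5, 5))
  expect_warning(tdio <- compute_tdi(list(out), dm, diag(4)), "outside")
  expect_true(all(which(tdio$counts > 0, arr.ind = TRUE) - 1L >= 0))
})

test_that("SPAM construction follows the binarize-sum-divide definition", {
  dm <- c(10L, 10L, 10L)
  mk_tdi <- function(vox, count) {
    counts <- array(0L, dm)
    counts[vox + 1L] <- as.integer(count)
    structure(list(counts = counts, affine = diag(4), dim = dm,
                   pair = c(1L, 2L), subject = NULL),
              class = "tdi_volume")
  }
  v <- rbind(c(1, 1, 1))
  # S = 1, a voxel crossed by 3 streamlines: count 1, probability 1
  one <- build_spam(list(mk_tdi(v, 3)))
  expect_equal(unname(one$spam$voxels[1, ]), c(1, 1, 1, 1))
  expect_equal(unname(one$spam$voxels[, "count"] / one$spam$nsubjects), 1)
  expect_equal(one$mean_tdi[2, 2, 2], 3)

  # S = 3, voxel present in 2 subjects: count 2, probability 2/3; the
  # mean TDI averages over all subjects including the absent one
  three <- build_spam(list(mk_tdi(v, 2), mk_tdi(v, 4)), nsubjects = 3)
  expect_equal(unname(three$spam$voxels[1, "count"]), 2)
  expect_equal(unname(three$spam$voxels[1, "count"] / 3), 2 / 3)
  expect_equal(three$mean_tdi[2, 2, 2], 2)

  bad <- mk_tdi(v, 1); bad$dim <- c(5L, 5L, 5L)
  expect_error(build_spam(list(mk_tdi(v, 1), bad)), "same grid")
})

test_that("SPAM equals brute-force subject-union counting on phantoms", {
  # dense independent counting on the 20-subject phantom
  res <- phantom20()
  a <- res$atlas
  dm <- a$header$dim
  for (key in names(a$spams)) {
    pairc <- a$spams[[key]]$pair
    e <- which(res$ground_truth$i == pairc[1] &
                 res$ground_truth$j == pairc[2])
    union_counts <- array(0L, dm)
    for (s in seq_along(res$tractograms)) {
      tr <- res$tractograms[[s]]
      sls <- tr$streamlines[tr$edge_index == e]
      support <- array(FALSE, dm)
      for (sl in sls) {
        vox <- slab_traversal_oracle(sl, dm)
        support[vox + 1L] <- TRUE
      }
      union_counts <- union_counts + support
    }
    sp <- a$spams[[key]]
    got <- array(0L, dm)
    got[sp$voxels[, 1:3] + 1L] <- sp$voxels[, "count"]
    expect_identical(got, union_counts)
    prob <- sp$voxels[, "count"] / sp$nsubjects
    expect_true(all(prob > 0 & prob <= 1))
  }
})

test_that("group matrices match a spreadsheet-style oracle", {
  cons <- group_connectivity(hand_connectomes())
  # consistency: subjects with nos > 0 per pair
  expect_equal(cons$consistency[1, 2], 3L)
  expect_equal(cons$consistency[1, 3], 2L)
  expect_equal(cons$consistency[1, 4], 1L)
  expect_equal(cons$consistency[2, 3], 3L)
  expect_equal(cons$consistency[2, 4], 2L)
  expect_equal(cons$consistency[3, 4], 2L)
  # mean NOS over all subjects
  expect_equal(cons$numbStlines[1, 2], (2 + 1 + 3) / 3)
  expect_equal(cons$numbStlines[1, 4], 1 / 3)
  # mean length over subjects having the connection
  expect_equal(cons$length[1, 2], 30)
  expect_equal(cons$length[1, 4], 70)
  expect_equal(cons$length[3, 4], 80)

  # a single subject duplicated: consistency = S on its support, means equal
  one <- hand_connectomes()[[1]]
  dup <- group_connectivity(rep(list(one), 5))
  expect_identical(dup$consistency, (one$nos > 0) * 5L)
  expect_equal(dup$numbStlines, one$nos)

  # 2 subjects, nos 4 and 0: consistency 1, mean NOS 2
  two <- hand_connectomes()[1:2]
  g2 <- group_connectivity(two)
  expect_equal(g2$consistency[1, 3], 1L)
  expect_equal(g2$numbStlines[1, 3], 0.5)
})

test_that("consensus thresholding reproduces an exhaustive hand evaluation", {
  conn <- hand_connectomes()
  group <- group_connectivity(conn)
  regions <- hand_regions()
  # 6 candidate edges, 2 equal-count length bins:
  #   bin 1 {30 (1,2), 40 (2,3), 50 (1,3)}, bin 2 {60 (2,4), 70 (1,4),
  #   80 (3,4)}; per-subject occupancy (3,2) / (2,2) / (3,1) gives
  #   targets round(8/3) = 3 and round(5/3) = 2; bin 2 keeps the two
  #   most consistent edges (2,4) and (3,4), dropping (1,4).
  ret <- consensus_threshold(conn, group, regions, c_min = 0, n_bins = 2)
  expect_identical(unname(ret),
                   rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(2L, 4L),
                         c(3L, 4L)))

  # c_min = 1 retains only pairs present in all subjects
  ret_all <- consensus_threshold(conn, group, regions, c_min = 1,
                                 n_bins = 2)
  full <- which(group$consistency == 3, arr.ind = TRUE)
  expect_true(all(ret_all[, 1] < ret_all[, 2]))
  for (r in seq_len(nrow(ret_all)))
    expect_equal(group$consistency[ret_all[r, 1], ret_all[r, 2]], 3L)

  # every subject has every connection: everything is retained
  dense_nos <- matrix(1, 4, 4); diag(dense_nos) <- 0
  lens <- matrix(10, 4, 4); diag(lens) <- 0
  dense <- rep(list(subject_connectome(dense_nos, lens, 1:4)), 3)
  gd <- group_connectivity(dense)
  retd <- consensus_threshold(dense, gd, regions, c_min = 0, n_bins = 2)
  expect_equal(nrow(retd), 6)

  # deterministic: repeated calls agree exactly
  expect_identical(ret,
                   consensus_threshold(conn, group, regions, 0, 2))
})

test_that("consensus preserves mean subject density per class on phantoms", {
  spec <- phantom_spec(
    seed = 303L,
    edges = rbind(c(1L, 3L), c(2L, 4L), c(1L, 2L), c(3L, 4L),
                  c(1L, 4L), c(2L, 3L)),
    presence = c(1, 0.9, 0.8, 0.7, 0.9, 0.6), rate = 3)
  p <- make_phantom_parcellation(spec)
  conn <- lapply(1:12, function(s)
    extract_bundles(simulate_subject_tractogram(p, spec, s),
                    p)$connectome)
  group <- group_connectivity(conn)
  n_bins <- 2L
  ret <- consensus_threshold(conn, group, p$table, c_min = 0,
                             n_bins = n_bins)
  expect_identical(ret, consensus_threshold(conn, group, p$table, 0,
                                            n_bins))
  hemi <- p$table$hemisphere[match(p$table$code, p$table$code)]
  class_of <- function(i, j) {
    hi <- p$table$hemisphere[match(i, p$table$code)]
    hj <- p$table$hemisphere[match(j, p$table$code)]
    if (hi == hj) "intra" else "inter"
  }
  for (cls in c("intra", "inter")) {
    kept <- sum(mapply(class_of, ret[, 1], ret[, 2]) == cls)
    per_subj <- vapply(conn, function(sc) {
      ut <- which(upper.tri(sc$nos) & sc$nos > 0, arr.ind = TRUE)
      if (nrow(ut) == 0) return(0)
      sum(mapply(class_of, sc$codes[ut[, 1]], sc$codes[ut[, 2]]) == cls)
    }, numeric(1))
    expect_lte(abs(kept - mean(per_subj)), 2 * n_bins)
  }
  # every retained pair is present in at least one subject
  for (r in seq_len(nrow(ret))) {
    i <- match(ret[r, 1], group$codes); j <- match(ret[r, 2], group$codes)
    expect_gte(group$consistency[i, j], 1L)
  }
})

test_that("atlas assembly enforces SPAM/retained-set coherence", {
  res <- phantom5()
  a <- res$atlas
  expect_equal(n_bundles(a), nrow(a$retained))

  # dropping a SPAM for a retained pair is an error
  broken <- a$spams[-1]
  expect_error(assemble_atlas(a$header, a$matrices, broken, a$retained),
               "missing SPAM")

  # an empty retained set still assembles into a valid zero-bundle atlas
  empty <- assemble_atlas(a$header, a$matrices, list(),
                          matrix(integer(), 0, 2))
  expect_equal(n_bundles(empty), 0)
  expect_error(atlas_density_summary(empty), NA)
})
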