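# Shared fixtures, cached so expensive phantom builds run once per suite.
.fixtures <- new.env(parent = emptyenv())

with_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 20-subject phantom atlas under the default study conditions
phantom20 <- function() {
  with_fixture("phantom20", function()
    build_phantom_atlas(phantom_spec(seed = 101L), nsubjects = 20L))
}

# small 5-subject phantom atlas for I/O and CLI tests
phantom5 <- function() {
  with_fixture("phantom5", function()
    build_phantom_atlas(phantom_spec(seed = 11L), nsubjects = 5L))
}

# jitter-free 3-subject phantom (identical bundles across subjects)
phantom3_nojitter <- function() {
  with_fixture("phantom3", function()
    build_phantom_atlas(phantom_spec(seed = 5L, jitter = 0),
                        nsubjects = 3L))
}

# quadratic arc between two points with a perpendicular apex offset
bezier_arc <- function(p0, p2, apex = c(0, 6, 0), m = 50L) {
  p1 <- (p0 + p2) / 2 + apex
  tt <- seq(0, 1, length.out = m)
  outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) + outer(tt^2, p2)
}

# random rigid transform (proper rotation + translation)
random_rigid <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  aff <- diag(4)
  aff[1:3, 1:3] <- q
  aff[1:3, 4] <- rnorm(3, 0, 10)
  aff
}

# Exact, independent voxel-traversal oracle: for every candidate voxel in
# the streamline's bounding box, slab-test every segment against the unit
# cube centered on the voxel (identity affine, 0-based indices).
slab_traversal_oracle <- function(s, dm) {
  lo <- pmax(0, floor(apply(s, 2, min)) - 1L)
  hi <- pmin(dm - 1L, ceiling(apply(s, 2, max)) + 1L)
  cand <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  hit <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(s) - 1L)) {
    p <- s[i, ]
    d <- s[i + 1L, ] - p
    tmin <- rep(0, nrow(cand))
    tmax <- rep(1, nrow(cand))
    ok <- rep(TRUE, nrow(cand))
    for (ax in 1:3) {
      loa <- cand[, ax] - 0.5
      hia <- cand[, ax] + 0.5
      if (d[ax] == 0) {
        ok <- ok & p[ax] >= loa & p[ax] <= hia
      } else {
        t1 <- (loa - p[ax]) / d[ax]
        t2 <- (hia - p[ax]) / d[ax]
        tmin <- pmax(tmin, pmin(t1, t2))
        tmax <- pmin(tmax, pmax(t1, t2))
      }
    }
    hit <- hit | (ok & tmin <= tmax)
  }
  v <- cand[hit, , drop = FALSE]
  v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
}

sort_voxels <- function(v) {
  v <- unname(as.matrix(v))
  v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
}
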