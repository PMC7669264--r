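test_that("grid construction covers the bounding box with centred voxels", {
  g <- make_grid(c(-78, -112, -70), c(78, 76, 85), 3)
  expect_identical(g$shape, c(53L, 63L, 52L))
  expect_equal(voxel_to_mm(g, c(0, 0, 0)), c(-78, -112, -70))

  g1 <- make_grid(c(0, 0, 0), c(0.5, 0.5, 0.5), 1)
  expect_identical(g1$shape, c(1L, 1L, 1L))
  expect_equal(voxel_to_mm(g1, c(0, 0, 0)), c(0, 0, 0))

  expect_error(make_grid(c(0, 0, 0), c(0, 1, 1), 1), "degenerate")
  expect_error(make_grid(c(0, 0, 0), c(1, 1, 1), -1), "positive")
})

test_that("mm/voxel transforms are exact inverses", {
  g <- make_grid(c(-78, -112, -70), c(78, 76, 85), 3)
  set.seed(42)
  ijk <- cbind(sample(0:52, 1000, TRUE), sample(0:62, 1000, TRUE),
               sample(0:51, 1000, TRUE))
  attr(ijk, "keep") <- TRUE
  back <- mm_to_voxel(g, voxel_to_mm(g, ijk))
  expect_lt(max(abs(back - ijk)), 1e-9)
})

test_that("sphere masks contain exactly the voxels within the radius", {
  g <- make_grid(c(-78, -112, -70), c(78, 76, 85), 3)
  # 6 mm sphere on a 3 mm grid centred on a voxel centre: i^2+j^2+k^2 <= 4
  s6 <- sphere_mask(g, c(-48, -58, -16), 6)
  expect_equal(mask_size(s6), 33L)
  s1 <- sphere_mask(g, c(-48, -58, -16), 1)
  expect_equal(mask_size(s1), 1L)
  # far outside the grid: empty mask allowed
  expect_equal(mask_size(sphere_mask(g, c(500, 500, 500), 6)), 0L)
})

test_that("sphere membership matches a brute-force distance scan", {
  g <- make_grid(c(-36, -36, -36), c(33, 33, 33), 3)  # 24^3
  set.seed(7)
  for (i in 1:50) {
    ctr <- runif(3, -30, 30)
    rad <- runif(1, 2, 14)
    expect_identical(sphere_mask(g, ctr, rad)$linear,
                     oracle_sphere_linear(g, ctr, rad))
  }
})

test_that("mirrored sphere centres give mirrored masks on a symmetric grid", {
  g <- make_grid(c(-60, -90, -45), c(60, 0, 15), 3)  # symmetric about x = 0
  a <- sphere_mask(g, c(-48, -57, -15), 6)
  b <- sphere_mask(g, c(48, -57, -15), 6)
  expect_equal(mask_size(a), mask_size(b))
  am <- mask_mm(a); bm <- mask_mm(b)
  expect_equal(sort(-am[, 1]), sort(bm[, 1]))
  expect_equal(sort(am[, 2]), sort(bm[, 2]))
})

test_that("mask set operations follow set arithmetic", {
  g <- make_grid(c(0, 0, 0), c(27, 27, 27), 3)
  a <- sphere_mask(g, c(9, 9, 9), 6)
  expect_identical(mask_intersect(a, a)$linear, a$linear)  # idempotent
  far <- sphere_mask(g, c(24, 24, 24), 3)
  expect_equal(mask_size(mask_intersect(a, far)), 0L)
  set.seed(11)
  for (i in 1:20) {
    la <- sample(prod(g$shape), 200)
    lb <- sample(prod(g$shape), 200)
    ma <- readcircuit:::new_mask(g, la); mb <- readcircuit:::new_mask(g, lb)
    expect_identical(mask_intersect(ma, mb)$linear,
                     sort(intersect(unique(la), unique(lb))))
    expect_identical(mask_union(ma, mb)$linear,
                     sort(union(la, lb)))
  }
  g2 <- make_grid(c(0, 0, 0), c(15, 15, 15), 3)
  expect_error(mask_intersect(a, sphere_mask(g2, c(6, 6, 6), 5)), "grids")
  expect_equal(mask_volume_mm3(a), mask_size(a) * 27)
})

test_that("connected components respect the connectivity convention", {
  g <- make_grid(c(0, 0, 0), c(12, 12, 12), 3)
  v <- numeric(prod(g$shape))
  lin <- function(i, j, k) i + g$shape[1] * (j + g$shape[2] * k) + 1
  # two face-sharing voxels: one cluster at any connectivity
  v[c(lin(1, 1, 1), lin(2, 1, 1))] <- 1
  for (cn in c(6, 18, 26))
    expect_length(connected_components(g, v, 0.5, cn), 1L)
  # two corner-sharing voxels: split at 18, joined at 26
  v <- numeric(prod(g$shape))
  v[c(lin(1, 1, 1), lin(2, 2, 2))] <- 1
  expect_length(connected_components(g, v, 0.5, 18), 2L)
  expect_length(connected_components(g, v, 0.5, 26), 1L)
  expect_length(connected_components(g, numeric(prod(g$shape)), 0.5), 0L)
  expect_error(connected_components(g, v, 0.5, 10), "connectivity")
})

test_that("component labelling agrees with an independent graph oracle", {
  g <- make_grid(c(0, 0, 0), c(45, 45, 45), 3)  # 16^3
  set.seed(13)
  all_ok <- TRUE
  for (i in 1:100) {
    v <- as.numeric(runif(prod(g$shape)) < 0.08)
    cn <- sample(c(6L, 18L, 26L), 1)
    cl <- connected_components(g, v, 0.5, cn)
    sizes <- sort(vapply(cl, `[[`, 1L, "size"), decreasing = TRUE)
    members <- sort(unlist(lapply(cl, function(x) x$mask$linear)))
    all_ok <- all_ok &&
      identical(sizes, oracle_cc_sizes(g$shape, which(v > 0.5), cn)) &&
      identical(members, which(v > 0.5)) &&     # partition property
      all(vapply(cl, function(x) x$peak_value == max(v[x$mask$linear]), TRUE))
    if (!all_ok) break
  }
  expect_true(all_ok)
})

test_that("cluster ordering is size-descending with deterministic ties", {
  g <- make_grid(c(0, 0, 0), c(30, 30, 30), 3)
  v <- numeric(prod(g$shape))
  lin <- function(i, j, k) i + g$shape[1] * (j + g$shape[2] * k) + 1
  v[c(lin(0, 0, 0), lin(1, 0, 0), lin(2, 0, 0))] <- 1      # size 3
  v[c(lin(5, 5, 5), lin(6, 5, 5))] <- 3                    # size 2, peak 3
  v[c(lin(8, 8, 8), lin(9, 8, 8))] <- 2                    # size 2, peak 2
  cl <- connected_components(g, v, 0.5, 18)
  expect_equal(vapply(cl, `[[`, 1L, "size"), c(3L, 2L, 2L))
  expect_equal(vapply(cl, `[[`, 0, "peak_value")[2:3], c(3, 2))
})

test_that("Gaussian smoothing is separable, renormalised and shape-safe", {
  g <- make_grid(c(0, 0, 0), c(15, 18, 12), 3)
  expect_equal(smooth_volume(g, rep(2.5, prod(g$shape)), 6),
               rep(2.5, prod(g$shape)))
  sh <- g$shape
  x <- array(rnorm(prod(sh)), sh)
  s1 <- smooth_volume(g, x, 6)
  gk <- function(n, sd) {
    d <- outer(1:n, 1:n, `-`); K <- exp(-d^2 / (2 * sd^2))
    K[abs(d) > ceiling(4 * sd)] <- 0; K / rowSums(K)
  }
  sd <- 6 / (2 * sqrt(2 * log(2))) / 3
  y <- x
  for (j in 1:sh[2]) for (k in 1:sh[3]) y[, j, k] <- gk(sh[1], sd) %*% x[, j, k]
  y2 <- y
  for (i in 1:sh[1]) for (k in 1:sh[3]) y2[i, , k] <- gk(sh[2], sd) %*% y[i, , k]
  y3 <- y2
  for (i in 1:sh[1]) for (j in 1:sh[2]) y3[i, j, ] <- gk(sh[3], sd) %*% y2[i, j, ]
  expect_lt(max(abs(s1 - y3)), 1e-12)
  # matrix form smooths each column like the single-volume form
  X <- cbind(as.vector(x), as.vector(x) * 2)
  S <- smooth_volume(g, X, 6)
  expect_equal(S[, 1], as.vector(s1))
  expect_equal(S[, 2], 2 * as.vector(s1))
})

test_that("NIfTI round trip preserves grid, values and mask datatype", {
  g <- make_grid(c(-12, -9, -6), c(9, 12, 15), 3)
  v <- rnorm(prod(g$shape))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(g, v, f)
  back <- read_volume(f)
  expect_equal(back$grid$shape, g$shape)
  expect_equal(back$grid$affine, g$affine, tolerance = 1e-6)
  expect_equal(back$values, v, tolerance = 1e-6)   # float32 storage
  expect_equal(unname(RNifti::niftiHeader(f)$datatype), 16L)

  m <- sphere_mask(g, c(0, 0, 0), 5)
  fm <- tempfile(fileext = ".nii.gz")
  write_mask(m, fm)
  expect_equal(unname(RNifti::niftiHeader(fm)$datatype), 2L)  # uint8
  mb <- read_volume(fm)
  expect_identical(which(mb$values == 1), m$linear)
  unlink(c(f, fm))
})
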