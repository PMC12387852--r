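test_that("dice identities: self, disjoint, and half-overlapping cubes", {
  a <- cube_mask(4L, pad = 2L, spacing = 0.25)
  expect_identical(dice(a, a), 1)
  b <- cube_mask(4L, pad = 2L, spacing = 0.25, offset = c(5L, 0L, 0L))
  expect_identical(dice(a, b), 0)
  # two 4x4x4 cubes offset by 2 voxels -> 2*32/(64+64)
  c2 <- cube_mask(4L, pad = 2L, spacing = 0.25, offset = c(2L, 0L, 0L))
  n_int <- sum(a$data & c2$data) # brute-force voxel count
  expect_identical(n_int, 32L)
  expect_identical(dice(a, c2), 2 * n_int / (sum(a$data) + sum(c2$data)))
  expect_identical(dice(a, c2), 0.5)
  # dice is symmetric; empty masks are identical by convention
  expect_identical(dice(c2, a), dice(a, c2))
  e <- seg_mask(array(FALSE, dim = dim(a$data)), grid = a)
  expect_identical(dice(e, e), 1)
  expect_error(dice(a, cube_mask(4L, pad = 2L, spacing = 0.5)), "grid")
})

test_that("hd95 matches the quadratic all-pairs oracle", {
  expect_identical(hd95(cube_mask(4L), cube_mask(4L)), 0)
  a <- cube_mask(8L, pad = 2L, spacing = 0.25)
  b <- cube_mask(8L, pad = 2L, spacing = 0.25, offset = c(4L, 0L, 0L))
  pa <- voxel_centers(a, which(oracle_boundary(a$data)))
  pb <- voxel_centers(b, which(oracle_boundary(b$data)))
  expect_equal(hd95(a, b), oracle_hd95(pa, pb), tolerance = 1e-12)
  set.seed(99)
  for (i in 1:10) {
    ra <- random_mask(c(6L, 6L, 6L), p = 0.4, spacing = c(0.3, 0.25, 0.5))
    rb <- random_mask(c(6L, 6L, 6L), p = 0.4, spacing = c(0.3, 0.25, 0.5))
    if (!any(ra$data) || !any(rb$data)) next
    pa <- voxel_centers(ra, which(oracle_boundary(ra$data)))
    pb <- voxel_centers(rb, which(oracle_boundary(rb$data)))
    expect_equal(hd95(ra, rb), oracle_hd95(pa, pb), tolerance = 1e-12)
    # symmetry of the pooled variant
    expect_identical(hd95(ra, rb), hd95(rb, ra))
    # 95th percentile never exceeds the exact Hausdorff distance
    exact_hd <- max(oracle_nn_dist(pa, pb), oracle_nn_dist(pb, pa))
    expect_lte(hd95(ra, rb), exact_hd + 1e-12)
    expect_lte(hd95(ra, rb, mode = "max_directed"), exact_hd + 1e-12)
  }
})

test_that("hd95 and rms are invariant under joint rigid motion", {
  R <- generic_rotation()
  a <- cube_mask(6L, pad = 2L, spacing = 0.25)
  b <- cube_mask(6L, pad = 2L, spacing = 0.25, offset = c(3L, 1L, 0L))
  h0 <- hd95(a, b)
  move <- function(m) seg_mask(m$data, spacing = m$spacing,
                               origin = as.numeric(R %*% m$origin + c(1, 2, 3)),
                               direction = R %*% m$direction)
  expect_equal(hd95(move(a), move(b)), h0, tolerance = 1e-9)
  pa <- voxel_centers(a, which(a$data))
  pb <- voxel_centers(b, which(b$data))
  r0 <- rms_distance(pa, pb)
  tp <- function(p) sweep(p %*% t(R), 2, c(1, 2, 3), `+`)
  expect_equal(rms_distance(tp(pa), tp(pb)), r0, tolerance = 1e-9)
})

test_that("rms_distance matches the brute-force oracle and its identities", {
  set.seed(21)
  a <- matrix(rnorm(600), ncol = 3)
  b <- matrix(rnorm(600), ncol = 3)
  expect_equal(rms_distance(a, b), sqrt(mean(oracle_nn_dist(a, b)^2)),
               tolerance = 1e-12)
  expect_identical(rms_distance(a, a), 0)
  # constant-offset plane: probes sit directly above sample points, all at
  # perpendicular distance 0.1
  g <- as.matrix(expand.grid(seq(-2, 2, 0.05), seq(-2, 2, 0.05)))
  plane <- cbind(g, 0)
  probe <- cbind(g[seq(1, nrow(g), 17), ], 0.1)
  expect_equal(rms_distance(probe, plane), 0.1, tolerance = 1e-3)
  # symmetric variant pools both directions
  expect_equal(rms_distance(a, b, symmetric = TRUE),
               sqrt(mean(c(oracle_nn_dist(a, b)^2, oracle_nn_dist(b, a)^2))),
               tolerance = 1e-12)
})

test_that("rigid_align recovers identity and a known transform", {
  set.seed(31)
  fixed <- matrix(runif(300, -10, 10), ncol = 3)
  same <- rigid_align(fixed, fixed)
  expect_equal(same$rotation, diag(3), tolerance = 1e-6)
  expect_equal(same$translation, c(0, 0, 0), tolerance = 1e-6)

  R10 <- rot_z(10)
  moved <- sweep(fixed %*% t(R10), 2, c(1, 2, 3), `+`)
  tr <- rigid_align(fixed, moved)
  recovered <- transform_points(tr, fixed)
  expect_lt(sqrt(mean(rowSums((recovered - moved)^2))), 1e-4)
  expect_equal(tr$rotation, R10, tolerance = 1e-4)
  expect_equal(tr$translation, c(1, 2, 3), tolerance = 1e-3)
})

test_that("ICP matched error is monotone and degenerate input is rejected", {
  set.seed(41)
  fixed <- matrix(runif(150, -5, 5), ncol = 3)
  moving <- sweep(fixed %*% t(rot_z(25)), 2, c(0.5, -1, 2), `+`)[1:40, ]
  rms_trace <- c()
  prev <- Inf
  for (it in 1:8) {
    tr <- rigid_align(moving, fixed, max_iter = it)
    rms_trace <- c(rms_trace, tr$rms)
  }
  expect_true(all(diff(rms_trace) <= 1e-9))
  # two points only -> collinear -> error
  expect_error(rigid_align(matrix(rnorm(6), 2, 3), fixed), "3 non-collinear")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(rigid_align(line, fixed), "collinear")
})
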