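test_that("build_voi derives plane normals from A->C and B->D", {
  pts <- control_points(A = c(0, 0, 0), B = c(0, 0, 10),
                        C = c(0, 0, -5), D = c(0, 0, 15))
  voi <- build_voi(pts)
  expect_equal(voi$lateral_plane$normal, c(0, 0, -1))
  expect_equal(voi$medial_plane$normal, c(0, 0, 1))
  expect_equal(voi$diameter, 20)

  pts2 <- control_points(A = c(0, 0, 0), B = c(0, 0, 10),
                         C = c(3, 0, 4), D = c(0, 0, 15))
  voi2 <- build_voi(pts2)
  expect_equal(voi2$lateral_plane$normal, c(0.6, 0, 0.8))
})

test_that("interior-side C triggers a warning, coincident C an error", {
  expect_error(control_points(c(0, 0, 0), c(0, 0, 10), c(0, 0, 0), c(0, 0, 15)),
               "C and A")
  pts <- control_points(A = c(0, 0, 0), B = c(0, 0, 10),
                        C = c(0, 0, 3), D = c(0, 0, 15))
  expect_warning(build_voi(pts), "interior")
})

test_that("voi_contains applies the radial and both plane tests inclusively", {
  pts <- control_points(A = c(0, 0, 0), B = c(0, 0, 10),
                        C = c(0, 0, -5), D = c(0, 0, 15))
  voi <- build_voi(pts, diameter = 20)
  expect_true(voi_contains(voi, c(9, 0, 5)))
  expect_false(voi_contains(voi, c(11, 0, 5)))
  expect_true(voi_contains(voi, c(0, 0, 0)))   # boundary inclusive at A
  expect_true(voi_contains(voi, c(10, 0, 5)))  # boundary inclusive radially
  expect_false(voi_contains(voi, c(0, 0, -0.1)))
  expect_false(voi_contains(voi, c(0, 0, 10.1)))
})

test_that("containment and rasterisation are monotone in diameter", {
  pts <- control_points(A = c(0, 0, 0), B = c(0, 0, 10),
                        C = c(0, 0, -5), D = c(0, 0, 15))
  set.seed(11)
  x <- cbind(runif(500, -12, 12), runif(500, -12, 12), runif(500, -3, 13))
  for (pair in list(c(4, 8), c(8, 16), c(16, 20))) {
    small <- voi_contains(build_voi(pts, pair[1]), x)
    large <- voi_contains(build_voi(pts, pair[2]), x)
    expect_true(all(large[small]))
  }
  grid <- image_volume(array(0, dim = c(40, 40, 50)),
                       spacing = rep(0.5, 3), origin = c(-9.75, -9.75, -2.25))
  m1 <- rasterize_voi(build_voi(pts, 6), grid)
  m2 <- rasterize_voi(build_voi(pts, 12), grid)
  expect_true(all(m2$data[m1$data]))
})

test_that("rasterised truncated-cylinder volume approaches the analytic value", {
  # axis slightly off the lattice symmetry axes so the discretisation error
  # behaves generically
  ctr <- c(0.08, 0.13)
  pts <- control_points(A = c(ctr, 0), B = c(ctr, 10),
                        C = c(ctr, -5), D = c(ctr, 15))
  voi <- build_voi(pts, diameter = 6)
  analytic <- pi * 3^2 * 10
  errs <- vapply(c(0.5, 0.25, 0.125), function(sp) {
    half <- 4.5
    n_xy <- 2 * ceiling(half / sp)
    n_z <- ceiling(12 / sp)
    grid <- image_volume(array(0, dim = c(n_xy, n_xy, n_z)),
                         spacing = rep(sp, 3),
                         origin = c(-half + sp / 2, -half + sp / 2, -1 + sp / 2))
    abs(mask_volume(rasterize_voi(voi, grid)) - analytic)
  }, 0)
  expect_lt(errs[2] / analytic, 0.03)
  expect_true(all(diff(errs) < 0))
})

test_that("a VOI thinner than a voxel between voxel centres raises", {
  pts <- control_points(A = c(0.5, 0.5, 0), B = c(0.5, 0.5, 10),
                        C = c(0.5, 0.5, -5), D = c(0.5, 0.5, 15))
  voi <- build_voi(pts, diameter = 0.2)
  grid <- image_volume(array(0, dim = c(10, 10, 12)), spacing = c(1, 1, 1))
  expect_error(rasterize_voi(voi, grid), "does not intersect")
})

test_that("the rasterised mask is equivariant under one-voxel translation", {
  pts <- control_points(A = c(0, 0, 1), B = c(0, 0, 7),
                        C = c(0, 0, -5), D = c(0, 0, 15))
  voi <- build_voi(pts, diameter = 4)
  grid <- image_volume(array(0, dim = c(24, 24, 30)),
                       spacing = rep(0.5, 3), origin = c(-5.75, -5.75, -2.75))
  m0 <- rasterize_voi(voi, grid)
  pts2 <- control_points(A = c(0, 0, 1.5), B = c(0, 0, 7.5),
                         C = c(0, 0, -4.5), D = c(0, 0, 15.5))
  m1 <- rasterize_voi(build_voi(pts2, 4), grid)
  expect_identical(m1$data[, , 2:30], m0$data[, , 1:29])
})

test_that("rotating grid and points together leaves the voxel set unchanged", {
  R <- generic_rotation()
  pts <- control_points(A = c(0, 0, 0), B = c(0, 0, 8),
                        C = c(0, 0, -5), D = c(0, 0, 13))
  grid <- image_volume(array(0, dim = c(20, 20, 24)),
                       spacing = rep(0.5, 3), origin = c(-4.75, -4.75, -1.75))
  m0 <- rasterize_voi(build_voi(pts, 5), grid)
  rpts <- control_points(R %*% pts$A, R %*% pts$B, R %*% pts$C, R %*% pts$D)
  rgrid <- image_volume(grid$data, spacing = grid$spacing,
                        origin = as.numeric(R %*% grid$origin),
                        direction = R %*% grid$direction)
  m1 <- rasterize_voi(build_voi(rpts, 5), rgrid)
  expect_identical(m1$data, m0$data)
})
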