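test_that("Gaussian smoothing preserves constants, mass, and peak location", {
  vol <- image_volume(array(100, dim = c(12, 12, 12)), spacing = rep(0.25, 3))
  sm <- smooth_volume(vol, 0.3)
  expect_equal(sm$data, vol$data, tolerance = 1e-9)

  imp <- image_volume(array(0, dim = c(21, 21, 21)), spacing = rep(0.25, 3))
  imp$data[11, 11, 11] <- 1
  sm2 <- smooth_volume(imp, 0.3)
  expect_equal(sum(sm2$data), 1, tolerance = 1e-6)
  expect_equal(which.max(sm2$data), which(imp$data == 1))

  expect_identical(smooth_volume(imp, 0)$data, imp$data)
  expect_error(smooth_volume(imp, -1), "sigma")
})

test_that("smoothing in mm adapts to anisotropic spacing", {
  # an impulse smoothed with sigma 0.6 mm must have equal world-space spread
  # along an axis with 0.3 mm spacing (2 voxels) and 0.6 mm spacing (1 voxel)
  vol <- image_volume(array(0, dim = c(31, 31, 31)),
                      spacing = c(0.3, 0.6, 0.3))
  vol$data[16, 16, 16] <- 1
  sm <- smooth_volume(vol, 0.6)
  px <- sm$data[, 16, 16]
  py <- sm$data[16, , 16]
  sd_x <- sqrt(sum(px / sum(px) * ((seq_len(31) - 16) * 0.3)^2))
  sd_y <- sqrt(sum(py / sum(py) * ((seq_len(31) - 16) * 0.6)^2))
  expect_equal(sd_x, sd_y, tolerance = 0.02)
  expect_equal(sd_x, 0.6, tolerance = 0.02)
})

test_that("thresholding is exact, monotone, and VOI-restricted", {
  ph <- generate_phantom(phantom_spec(noise_sd = 0))
  voi <- build_voi(ph$suggested_points)
  voi_mask <- rasterize_voi(voi, ph$volume)
  p <- seg_params(threshold = -300)
  m <- threshold_in_voi(ph$volume, voi_mask, p)
  expect_identical(m$data, (ph$volume$data <= -300) & voi_mask$data)
  # below the global minimum: empty
  m0 <- threshold_in_voi(ph$volume, voi_mask, seg_params(threshold = -2000))
  expect_equal(sum(m0$data), 0L)
  # monotone in the threshold
  m1 <- threshold_in_voi(ph$volume, voi_mask, seg_params(threshold = -300))
  m2 <- threshold_in_voi(ph$volume, voi_mask, seg_params(threshold = 500))
  expect_true(all(m2$data[m1$data]))
})

test_that("6-connectivity joins faces but not edges", {
  m <- array(FALSE, dim = c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE # edge-adjacent only
  expect_equal(label_components(seg_mask(m))$count, 2L)
  m2 <- array(FALSE, dim = c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 1, 1] <- TRUE # face-adjacent
  expect_equal(label_components(seg_mask(m2))$count, 1L)
})

test_that("component labelling matches a brute-force flood fill on random masks", {
  set.seed(123)
  for (i in 1:50) {
    mask <- random_mask(c(8L, 8L, 8L), p = runif(1, 0.2, 0.6))
    res <- label_components(mask)
    oracle <- oracle_flood_fill6(mask$data)
    expect_equal(res$count, max(oracle))
    expect_true(same_partition(res$labels, oracle))
  }
})

test_that("component mean segment-distance matches per-voxel brute force", {
  set.seed(5)
  mask <- random_mask(c(8L, 8L, 8L), p = 0.3, spacing = c(0.4, 0.25, 0.6))
  lab <- label_components(mask)
  pts <- control_points(A = c(0.1, 0.2, 0.3), B = c(2, 1.5, 4),
                        C = c(-3, 0, 0), D = c(5, 3, 8))
  sel <- select_component(lab, mask, pts)
  for (k in seq_len(lab$count)) {
    idx <- which(lab$labels == k)
    bf <- mean(oracle_segment_distance(voxel_centers(mask, idx), pts$A, pts$B))
    expect_equal(sel$reports$mean_line_distance[k], bf, tolerance = 1e-12)
  }
  expect_equal(sum(sel$reports$selected), 1L)
  expect_equal(sel$reports$label[sel$reports$selected],
               sel$reports$label[which.min(sel$reports$mean_line_distance)])
})

test_that("the component nearest the A-B segment is selected; ties break by label", {
  # two tubes at 2 mm and 8 mm from the axis
  d <- c(40L, 40L, 20L)
  m <- array(FALSE, dim = d)
  grid <- image_volume(array(0, dim = d), spacing = rep(0.5, 3),
                       origin = c(-9.75, -9.75, 0.25))
  xyz <- voxel_centers(grid)
  near <- sqrt((xyz[, 1] - 2)^2 + xyz[, 2]^2) <= 1.2
  far <- sqrt((xyz[, 1] - 8)^2 + xyz[, 2]^2) <= 1.2
  mask <- seg_mask(array(near | far, dim = d), grid = grid)
  lab <- label_components(mask)
  expect_equal(lab$count, 2L)
  pts <- control_points(A = c(0, 0, 0), B = c(0, 0, 10),
                        C = c(0, 0, -5), D = c(0, 0, 15))
  sel <- select_component(lab, mask, pts)
  sel_label <- sel$reports$label[sel$reports$selected]
  near_label <- lab$labels[which(array(near, dim = d))[1]]
  expect_equal(sel_label, near_label)

  # exact mirror symmetry: equal distance, equal size -> smaller label wins
  sym <- sqrt((xyz[, 1] - 4)^2 + xyz[, 2]^2) <= 1.2 |
         sqrt((xyz[, 1] + 4)^2 + xyz[, 2]^2) <= 1.2
  mask2 <- seg_mask(array(sym, dim = d), grid = grid)
  lab2 <- label_components(mask2)
  expect_equal(lab2$count, 2L)
  sel2 <- select_component(lab2, mask2, pts)
  expect_equal(sel2$reports$label[sel2$reports$selected], 1L)

  expect_error(select_component(list(labels = array(0L, d), count = 0L),
                                mask, pts), "no candidate region")
})

test_that("noise-free default phantom is recovered almost perfectly", {
  ph <- generate_phantom()
  seg <- segment_eec(ph$volume, ph$suggested_points)
  expect_gte(dice(seg$mask, ph$truth_mask), 0.95)
  # single component, subset of the VOI
  expect_equal(label_components(seg$mask)$count, 1L)
  voi_mask <- rasterize_voi(seg$voi, ph$volume)
  expect_true(all(voi_mask$data[seg$mask$data]))
})

test_that("with sigma 0 and no noise the segmentation equals ground truth", {
  ph <- generate_phantom()
  seg <- segment_eec(ph$volume, ph$suggested_points, seg_params(sigma = 0))
  expect_identical(seg$mask$data, ph$truth_mask$data)
})

test_that("selected-component volume is monotone in the threshold", {
  ph <- generate_phantom()
  vols <- vapply(c(-600, -200, 200), function(thr) {
    seg <- segment_eec(ph$volume, ph$suggested_points,
                       seg_params(threshold = thr))
    mask_volume(seg$mask)
  }, 0)
  expect_true(all(diff(vols) >= 0))
})

test_that("a medial plane placed beyond the membrane swallows the middle ear", {
  ph <- generate_phantom()
  spec <- ph$spec
  # move B (and D) past the membrane into the middle-ear cavity
  shift <- spec$membrane_thickness + 2 * spec$middle_ear_radius + 0.5
  pts <- ph$suggested_points
  pts_bad <- control_points(A = pts$A, B = pts$B + c(0, 0, shift),
                            C = pts$C, D = pts$D + c(0, 0, shift))
  seg <- segment_eec(ph$volume, pts_bad)
  expect_gt(mask_volume(seg$mask), 1.5 * mask_volume(ph$truth_mask))
})

test_that("a threshold below air fails with a stage-named error", {
  ph <- generate_phantom()
  expect_error(segment_eec(ph$volume, ph$suggested_points,
                           seg_params(threshold = -2000)),
               "no candidate region")
})
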