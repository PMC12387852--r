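test_that("NRRD write/read round trip is lossless for integer data", {
  a <- array(as.integer(sample.int(1000, 64)), dim = c(4, 4, 4))
  vol <- image_volume(a, spacing = c(0.25, 0.3, 0.5), origin = c(-1, 2, 3.5))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_identical(back$data, a)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-9)
  expect_equal(back$origin, vol$origin, tolerance = 1e-9)
  expect_equal(back$direction, vol$direction, tolerance = 1e-9)
})

test_that("NIfTI round trip preserves data and geometry, including rotation", {
  R <- rot_z(30)
  a <- array(as.integer(1:60), dim = c(3, 4, 5))
  vol <- image_volume(a, spacing = c(0.25, 0.25, 0.5),
                      origin = c(5, -3, 1), direction = R)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_equal(as.integer(back$data), as.integer(a))
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-5)
  expect_equal(back$origin, vol$origin, tolerance = 1e-5)
  expect_equal(back$direction, vol$direction, tolerance = 1e-5)
})

test_that("NIfTI RAS affine is converted to the internal LPS frame", {
  # write a NIfTI with RAS affine diag(0.25) and origin (1,2,3) directly
  img <- RNifti::asNifti(array(0L, dim = c(4, 4, 4)))
  aff <- structure(rbind(cbind(diag(c(0.25, 0.25, 0.25)), c(1, 2, 3)),
                         c(0, 0, 0, 1)), code = 2L)
  RNifti::pixdim(img) <- c(0.25, 0.25, 0.25)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  p <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, p)
  vol <- read_volume(p)
  expect_equal(vol$origin, c(-1, -2, 3), tolerance = 1e-6)
  expect_equal(vol$spacing, c(0.25, 0.25, 0.25), tolerance = 1e-6)
})

test_that("RAS<->LPS conversion is an involution", {
  set.seed(7)
  pts <- matrix(rnorm(30), ncol = 3)
  expect_identical(ras_lps(ras_lps(pts)), pts)
  v <- c(3, -4, 5)
  expect_identical(ras_lps(ras_lps(v)), v)
  expect_equal(ras_lps(v), c(-3, 4, 5))
})

test_that("DICOM series written by an independent tool reads correctly", {
  dir <- withr::local_tempdir()
  write_dicom_series_fixture(dir, n_slices = 10L, rows = 12L, cols = 16L,
                             pixel_spacing = c(0.3, 0.35),
                             slice_spacing = 0.5, origin = c(1, 2, 3))
  vol <- read_volume(dir, format = "dicom_dir")
  expect_equal(dim(vol$data), c(16L, 12L, 10L))
  # spacing: (col spacing, row spacing, slice spacing)
  expect_equal(vol$spacing, c(0.35, 0.3, 0.5), tolerance = 1e-6)
  expect_equal(vol$origin, c(1, 2, 3), tolerance = 1e-6)
  expect_equal(vol$direction, diag(3), tolerance = 1e-9)
  # pixel values: slice k, row r, col c -> k*1000 + r*16 + c, minus the
  # rescale intercept of -1000
  expect_equal(vol$data[1, 1, 1], 0 - 1000)
  expect_equal(vol$data[5, 3, 2], 1000 + 2 * 16 + 4 - 1000)
  expect_equal(vol$data[16, 12, 10], 9 * 1000 + 11 * 16 + 15 - 1000)
})

test_that("inconsistent DICOM slice spacing is rejected", {
  dir <- withr::local_tempdir()
  write_dicom_series_fixture(dir, n_slices = 4L, slice_spacing = 0.5)
  # add a far-away duplicate-geometry slice by shifting one file's position:
  # easier: write a second series with different spacing into the same dir
  write_dicom_series_fixture(file.path(dir, "extra"), n_slices = 2L,
                             slice_spacing = 0.8, origin = c(1, 2, 30))
  file.copy(list.files(file.path(dir, "extra"), full.names = TRUE),
            file.path(dir, c("zz1.dcm", "zz2.dcm")))
  unlink(file.path(dir, "extra"), recursive = TRUE)
  expect_error(read_volume(dir, format = "dicom_dir"),
               "inconsistent slice spacing")
})

test_that("unreadable volume paths raise clear errors", {
  expect_error(read_volume(tempfile(fileext = ".nii.gz")), "does not exist")
  p <- withr::local_tempfile(fileext = ".nrrd")
  writeLines("not an nrrd", p)
  expect_error(read_volume(p), "magic")
})

test_that("volume containers validate their invariants", {
  expect_error(image_volume(array(0, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "spacing")
  bad_dir <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 2), 3, 3)
  expect_error(image_volume(array(0, c(2, 2, 2)), direction = bad_dir),
               "orthonormal")
  expect_error(seg_mask(array(2, c(2, 2, 2))), "0/1")
})
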