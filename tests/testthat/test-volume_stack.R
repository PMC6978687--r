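test_that("NIfTI round trip preserves data, spacing and affine", {
  arr <- array(rnorm(6 * 5 * 4), dim = c(6, 5, 4))
  affine <- rbind(cbind(diag(c(0.37, 0.37, 5.5)), c(-10, 4, 2)), c(0, 0, 0, 1))
  for (ext in c(".nii", ".nii.gz")) {
    p <- withr::local_tempfile(fileext = ext)
    write_nifti(arr, p, spacing = c(0.37, 0.37, 5.5), affine = affine,
                datatype = "float64")
    back <- read_nifti(p)
    expect_identical(back$data, arr)
    expect_equal(back$spacing, c(0.37, 0.37, 5.5), tolerance = 1e-6)
    expect_equal(back$affine, affine, tolerance = 1e-6)
  }
  # integer volumes stored as int32 come back exact
  lab <- array(sample.int(5L, 120, replace = TRUE), dim = c(6, 5, 4))
  p <- withr::local_tempfile(fileext = ".nii")
  write_nifti(lab, p, datatype = "int32")
  expect_identical(as.integer(read_nifti(p)$data), as.integer(lab))
})

test_that("stacking identical files yields identical feature slices", {
  arr <- array(runif(4 * 4 * 2), dim = c(4, 4, 2))
  p1 <- withr::local_tempfile(fileext = ".nii")
  p2 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(arr, p1, datatype = "float64")
  write_nifti(arr, p2, datatype = "float64")
  vol <- load_feature_volumes(c(p1, p2))
  expect_identical(vol$data[, , , 1], vol$data[, , , 2])
  expect_identical(dim(vol$data)[4], 2L)
})

test_that("a single feature volume is rejected unless overridden", {
  arr <- array(runif(8), dim = c(2, 2, 2))
  p <- withr::local_tempfile(fileext = ".nii")
  write_nifti(arr, p, datatype = "float64")
  expect_error(load_feature_volumes(p), "at least 2")
  vol <- load_feature_volumes(p, allow_single = TRUE)
  expect_identical(dim(vol$data)[4], 1L)
})

test_that("mismatched grids are reported with the offending files", {
  p1 <- withr::local_tempfile(fileext = ".nii")
  p2 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(array(0, dim = c(4, 4, 2)), p1, datatype = "float64")
  write_nifti(array(0, dim = c(5, 4, 2)), p2, datatype = "float64")
  expect_error(load_feature_volumes(c(p1, p2)), "4x4x2.*5x4x2|not on one grid")
})

test_that("a NaN voxel is excluded from the voxel table", {
  arr1 <- array(runif(16), dim = c(4, 4, 1))
  arr2 <- array(runif(16), dim = c(4, 4, 1))
  arr2[2, 3, 1] <- NaN
  vol <- feature_volume(array(c(arr1, arr2), dim = c(4, 4, 1, 2)), c(1, 1, 1))
  tab <- build_voxel_table(vol)
  expect_identical(nrow(tab$features), 15L)
  expect_false(any(tab$coords[, 1] == 2 & tab$coords[, 2] == 3))
  expect_true(all(is.finite(tab$features)))
})

test_that("resampling to the current spacing is the identity", {
  ph <- generate_phantom(small_phantom_spec())
  out <- resample_to_grid(ph$volume, ph$volume$spacing)
  expect_equal(out$data, ph$volume$data, tolerance = 1e-6)
})

test_that("resampling hits the requested spacing and preserves constants and extent", {
  arr <- array(7, dim = c(8, 8, 4, 2))
  vol <- feature_volume(arr, spacing = c(1, 1, 2))
  out <- resample_to_grid(vol, c(2, 2, 2))
  expect_equal(out$spacing, c(2, 2, 2))
  expect_true(all(abs(out$data - 7) < 1e-9))
  # world extent preserved within one voxel
  expect_true(all(abs(dim(out$data)[1:3] * out$spacing - c(8, 8, 4) * c(1, 1, 2)) <= c(2, 2, 2)))
  # a realistic anisotropic MRI spacing is representable
  out2 <- resample_to_grid(vol, c(0.37, 0.37, 5.5))
  expect_equal(out2$spacing, c(0.37, 0.37, 5.5))
})

test_that("upsampling a linear ramp interpolates linearly", {
  ramp <- array(rep(seq_len(8), times = 4 * 2), dim = c(8, 4, 2, 1))
  vol <- feature_volume(ramp, spacing = c(2, 2, 2))
  out <- resample_to_grid(vol, c(1, 2, 2))
  # voxel centers at x_world = 0,1,2,... -> input index 1, 1.5, 2, ...
  expect_equal(out$data[1:5, 1, 1, 1], c(1, 1.5, 2, 2.5, 3), tolerance = 1e-9)
})

test_that("voxel table row count matches mask census and round-trips to the grid", {
  ph <- generate_phantom(small_phantom_spec())
  tab <- build_voxel_table(ph$volume)
  expect_identical(nrow(tab$features), sum(ph$truth$data > 0))
  # full-mask count equals voxel count
  expect_identical(nrow(tab$features), as.integer(prod(dim(ph$volume$data)[1:3])))
  # scatter back reproduces the masked volume exactly
  for (f in c(1L, ncol(tab$features))) {
    back <- scatter_to_grid(tab, tab$features[, f], fill = NA)
    expect_identical(back[!is.na(back)], as.vector(ph$volume$data[, , , f]))
  }
})

test_that("an explicit mask restricts the table to exactly those voxels", {
  arr <- array(runif(4 * 4 * 1 * 2), dim = c(4, 4, 1, 2))
  vol <- feature_volume(arr, c(1, 1, 1))
  m <- array(0L, dim = c(4, 4, 1))
  picks <- rbind(c(1, 1, 1), c(2, 2, 1), c(3, 1, 1), c(4, 4, 1),
                 c(1, 3, 1), c(2, 4, 1), c(3, 3, 1))
  m[picks] <- 1L
  tab <- build_voxel_table(vol, mask = label_volume(m, legend = c(roi = 1L)))
  expect_identical(nrow(tab$features), 7L)
  expect_setequal(paste(tab$coords[, 1], tab$coords[, 2]), paste(picks[, 1], picks[, 2]))
  empty <- label_volume(array(0L, dim = c(4, 4, 1)))
  expect_error(build_voxel_table(vol, mask = empty), "empty")
})

test_that("manifest loading maps names to paths", {
  dir <- withr::local_tempdir()
  for (nm in c("adc", "cbf")) {
    write_nifti(array(runif(8), dim = c(2, 2, 2)), file.path(dir, paste0(nm, ".nii")),
                datatype = "float64")
  }
  manifest <- file.path(dir, "m.tsv")
  writeLines(c("adc\tadc.nii", "cbf\tcbf.nii"), manifest)
  vol <- load_feature_volumes(manifest)
  expect_identical(vol$feature_names, c("adc", "cbf"))
})
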