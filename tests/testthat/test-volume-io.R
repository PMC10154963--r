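make_test_volume <- function(dims = c(8, 8, 4), spacing = 0.107, seed = 3) {
  set.seed(seed)
  hu <- array(round(runif(prod(dims), -1000, 400)), dims)
  ct_volume(hu, spacing = spacing, source = "test")
}

test_that("Analyze 7.5 pairs round-trip voxel values and spacing", {
  v <- make_test_volume()
  stem <- file.path(withr::local_tempdir(), "vol")
  write_volume(v, stem, format = "analyze")
  expect_true(file.exists(paste0(stem, ".hdr")))
  r <- read_volume(paste0(stem, ".hdr"), format = "analyze")
  expect_equal(r$dims, c(8L, 8L, 4L))
  expect_equal(r$spacing, rep(0.107, 3), tolerance = 1e-6)
  expect_equal(r$voxels, v$voxels, tolerance = 1e-6)
})

test_that("missing Analyze header or image is reported by name", {
  d <- withr::local_tempdir()
  expect_error(read_volume(file.path(d, "nope.hdr"), format = "analyze"),
               "missing Analyze header")
  file.create(file.path(d, "img_only.hdr"))
  expect_error(read_volume(file.path(d, "img_only.hdr"), format = "analyze"),
               "missing Analyze image")
})

test_that("TIFF stacks round-trip integer HU and warn about missing spacing", {
  v <- make_test_volume()
  path <- file.path(withr::local_tempdir(), "vol.tif")
  write_volume(v, path, format = "tiff_stack")
  expect_warning(r <- read_volume(path, format = "tiff_stack"),
                 "defaulting to 0.107")
  expect_equal(r$voxels, v$voxels)
  r2 <- read_volume(path, format = "tiff_stack", spacing = 0.2)
  expect_equal(r2$spacing, rep(0.2, 3))
})

test_that("DICOM series round-trip and apply rescale slope/intercept", {
  v <- make_test_volume(dims = c(8, 6, 5))
  d <- file.path(withr::local_tempdir(), "dcm")
  # stored values are offset by the intercept: HU -500 <-> stored 524
  write_volume(v, d, format = "dicom_dir", rescale_intercept = -1024)
  r <- read_volume(d, format = "dicom_dir")
  expect_equal(r$voxels, v$voxels)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-9)

  single <- ct_volume(array(-500, c(4, 4, 2)), spacing = 0.107)
  d2 <- file.path(withr::local_tempdir(), "dcm2")
  write_volume(single, d2, format = "dicom_dir", rescale_intercept = -1024)
  slice <- ctlung:::read_dicom_slice(list.files(d2, full.names = TRUE)[1])
  expect_equal(unique(as.vector(slice$pixels)), -500)  # 524 * 1 + (-1024)
})

test_that("the same physical volume reads identically from all three formats", {
  v <- make_test_volume(dims = c(10, 10, 6))
  d <- withr::local_tempdir()
  write_volume(v, file.path(d, "vol"), format = "analyze")
  write_volume(v, file.path(d, "vol.tif"), format = "tiff_stack")
  write_volume(v, file.path(d, "dcm"), format = "dicom_dir")
  a <- read_volume(file.path(d, "vol.hdr"))
  t <- read_volume(file.path(d, "vol.tif"), spacing = v$spacing)
  dc <- read_volume(file.path(d, "dcm"))
  expect_equal(a$voxels, t$voxels, tolerance = 1e-6)
  expect_equal(t$voxels, dc$voxels)
  expect_equal(a$spacing, dc$spacing, tolerance = 1e-6)
})

test_that("inconsistent DICOM slice spacing is a geometry error", {
  v <- make_test_volume(dims = c(4, 4, 4))
  d <- file.path(withr::local_tempdir(), "dcm")
  write_volume(v, d, format = "dicom_dir")
  # corrupt one slice's z position by > 1% of the step
  f <- list.files(d, full.names = TRUE)[4]
  sl <- ctlung:::read_dicom_slice(f)
  v2 <- ct_volume(array(0, c(4, 4, 1)), spacing = v$spacing)
  ctlung:::write_dicom_dir(v2, file.path(d, "extra"))
  file.copy(list.files(file.path(d, "extra"), full.names = TRUE)[1],
            file.path(d, "slice0099.dcm"))
  unlink(file.path(d, "extra"), recursive = TRUE)
  expect_error(read_volume(d, format = "dicom_dir"), "geometry error")
})

test_that("mask export round-trips in both formats and rejects unknown tokens", {
  ph <- phantom_small()
  d <- withr::local_tempdir()
  for (fmt in c("nifti", "tiff_stack")) {
    ext <- if (fmt == "nifti") "nii.gz" else "tif"
    p <- file.path(d, paste0("mask.", ext))
    write_mask(ph$truth, p, format = fmt)
    expect_identical(read_mask(p, format = fmt), unname(ph$truth$mask))
  }
  zero <- array(FALSE, c(4, 4, 2))
  p0 <- file.path(d, "zero.nii.gz")
  write_mask(zero, p0)
  expect_identical(read_mask(p0), zero)
  expect_error(write_mask(zero, file.path(d, "x"), format = "hdf5"))
})

test_that("measurement tables round-trip through CSV within 1e-9", {
  ph <- phantom_small()
  tab <- measure_bins(ph$volume, ph$truth, hu_bin_scheme("mod"),
                      volume_id = "ph1")
  p <- file.path(withr::local_tempdir(), "t.csv")
  write_measurements(tab, p)
  lines <- readLines(p)
  expect_equal(lines[1], "volume_id,slice,bin_label,voxel_count,measure_mm,fraction")
  back <- read_measurements(p)
  expect_equal(back$voxel_count, tab$voxel_count)
  expect_equal(back$measure_mm, tab$measure_mm, tolerance = 1e-9)
  expect_equal(back$fraction, tab$fraction, tolerance = 1e-9)

  one <- tab[1, ]
  write_measurements(one, p)
  expect_length(readLines(p), 2L)
  expect_error(write_measurements(tab[0, ], p), "empty")
})
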