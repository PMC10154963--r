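test_that("per-bin volume is voxel count times the voxel volume", {
  v <- ct_volume(array(-650, c(10, 10, 10)), spacing = 0.107)
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- TRUE
  tab <- measure_bins(v, m, hu_bin_scheme("default"))
  row <- tab[tab$bin_label == "[-1000,-600)", ]
  expect_equal(row$voxel_count, 1000)
  expect_equal(row$measure_mm, 1000 * 0.107^3)  # 1.225043 mm^3
  expect_equal(row$fraction, 1)
  empty <- tab[tab$bin_label == "[-200,0]", ]
  expect_equal(empty$voxel_count, 0)
  expect_equal(empty$fraction, 0)
})

test_that("bin counts are conserved and fractions sum to one", {
  ph <- phantom_small()
  seg <- segment_lung(ph$volume, base_slice = ph$base_slice)
  for (scheme in list(hu_bin_scheme("default"), hu_bin_scheme("mod"))) {
    tab <- measure_bins(ph$volume, seg, scheme)
    rows <- tab[tab$bin_label != "TOTAL", ]
    expect_identical(as.integer(sum(rows$voxel_count)), sum(seg$mask))
    expect_lt(abs(sum(rows$fraction) - 1), 1e-9)
  }
})

test_that("total tissue volume excludes the out-of-range row", {
  tab <- data.frame(volume_id = "v", slice = "ALL",
                    bin_label = c("a", "b", OUT_OF_RANGE, "TOTAL"),
                    voxel_count = c(1, 2, 5, 3),
                    measure_mm = c(1, 2, 5, 3), fraction = c(.1, .2, .5, .3))
  expect_equal(total_tissue_volume(tab), 3)
  oor <- tab[3, ]
  expect_equal(total_tissue_volume(oor), 0)
})

test_that("slice ROI measurement matches direct arithmetic", {
  v <- ct_volume(array(-450, c(20, 20, 5)), spacing = 0.107)
  m2 <- matrix(FALSE, 20, 20); m2[1:10, 1:10] <- TRUE  # 100 pixels
  tab <- measure_slice_roi(v, slice_roi(3, m2), hu_bin_scheme("default"))
  tot <- tab[tab$bin_label == "TOTAL", ]
  expect_equal(tot$voxel_count, 100)
  expect_equal(tot$measure_mm, 100 * 0.107^2)  # 1.1449 mm^2
  expect_equal(tab$slice, rep("3", nrow(tab)))

  empty <- measure_slice_roi(v, slice_roi(1, matrix(FALSE, 20, 20)))
  expect_true(all(empty$voxel_count == 0))
  expect_error(measure_slice_roi(v, slice_roi(9, m2)), "outside stack")
  expect_error(measure_slice_roi(v, slice_roi(2, matrix(TRUE, 5, 5))),
               "geometry error")
})

test_that("a full-slice ROI equals the volume measurement of that slice", {
  ph <- phantom_small()
  scheme <- hu_bin_scheme("mod")
  s <- 40L
  full <- matrix(TRUE, ph$volume$dims[1], ph$volume$dims[2])
  roi_tab <- measure_slice_roi(ph$volume, slice_roi(s, full), scheme)
  m <- array(FALSE, ph$volume$dims); m[, , s] <- TRUE
  vol_tab <- measure_bins(ph$volume, m, scheme)
  expect_equal(roi_tab$voxel_count, vol_tab$voxel_count)
})

test_that("summing per-slice measurements reproduces the volume table", {
  ph <- phantom_small()
  scheme <- hu_bin_scheme("default")
  seg <- segment_lung(ph$volume, base_slice = ph$base_slice)
  vol_tab <- measure_bins(ph$volume, seg, scheme)
  occ <- which(apply(seg$mask, 3, any))
  slice_counts <- Reduce(`+`, lapply(occ, function(s) {
    measure_slice_roi(ph$volume, slice_roi(s, seg$mask[, , s]),
                      scheme)$voxel_count
  }))
  expect_equal(slice_counts, vol_tab$voxel_count)
  # areas x slice spacing = volumes
  areas <- Reduce(`+`, lapply(occ, function(s) {
    measure_slice_roi(ph$volume, slice_roi(s, seg$mask[, , s]),
                      scheme)$measure_mm
  }))
  expect_equal(areas * ph$volume$spacing[3], vol_tab$measure_mm,
               tolerance = 1e-9)
})

test_that("doubling the spacing scales volumes by 8 and areas by 4", {
  ph <- phantom_small()
  v2 <- ct_volume(ph$volume$voxels, spacing = 2 * ph$volume$spacing)
  t1 <- measure_bins(ph$volume, ph$truth$mask)
  t2 <- measure_bins(v2, ph$truth$mask)
  expect_equal(t2$voxel_count, t1$voxel_count)
  expect_equal(t2$measure_mm, 8 * t1$measure_mm)
  s <- ph$base_slice + 5L
  r1 <- measure_slice_roi(ph$volume, slice_roi(s, ph$truth$mask[, , s]))
  r2 <- measure_slice_roi(v2, slice_roi(s, ph$truth$mask[, , s]))
  expect_equal(r2$measure_mm, 4 * r1$measure_mm)
})

test_that("ROI augmentation re-anchors at the offset slices only", {
  roi <- slice_roi(100, matrix(TRUE, 4, 4), "a1")
  aug <- augment_roi(roi, n_slices = 300)
  expect_length(aug, 2L)
  expect_equal(vapply(aug, `[[`, integer(1), "slice_index"), c(95L, 105L))
  expect_identical(aug[[1]]$mask2d, roi$mask2d)
  expect_equal(aug[[1]]$analyst_id, "a1")

  low <- slice_roi(2, matrix(TRUE, 4, 4))
  expect_warning(a2 <- augment_roi(low, c(-5L, 5L), n_slices = 300), "dropped")
  expect_length(a2, 1L)
  expect_equal(a2[[1]]$slice_index, 7L)
  expect_length(augment_roi(roi, integer(0), n_slices = 300), 0L)
})

test_that("polygon ROIs rasterize with the even-odd rule", {
  # 4 x 4 axis-aligned square: pixel centers strictly inside
  sq <- roi_from_polygon(1, rbind(c(2.5, 2.5), c(6.5, 2.5),
                                  c(6.5, 6.5), c(2.5, 6.5)), c(8, 8))
  expect_equal(sum(sq$mask2d), 16L)
  expect_true(all(sq$mask2d[3:6, 3:6]))
  expect_error(roi_from_polygon(1, rbind(c(1, 1), c(2, 2)), c(8, 8)),
               "n >= 3")
})
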