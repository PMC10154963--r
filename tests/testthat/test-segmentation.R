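test_that("threshold mask is closed on both ends and validates bounds", {
  hu <- array(c(-1200, -500, -100, 50, -200, -32768, rep(0, 2)), c(2, 2, 2))
  expect_warning(ct_volume(hu), "below -1024")  # padding values are flagged
  v <- suppressWarnings(ct_volume(hu))
  m <- threshold_mask(v)
  expect_identical(as.vector(m)[1:6], c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  one <- threshold_mask(v, lo = -500, hi = -500)
  expect_identical(sum(one), 1L)
  expect_error(threshold_mask(v, lo = 0, hi = -1), "lo must be <= hi")
})

test_that("raising the upper threshold never deselects a voxel", {
  set.seed(21)
  v <- array(runif(512, -1100, 300), c(8, 8, 8))
  his <- c(-500, -300, -200, -100, 0)
  prev <- threshold_mask(v, hi = his[1])
  for (hi in his[-1]) {
    cur <- threshold_mask(v, hi = hi)
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("connectivity definitions: corners join under 26 but not 6", {
  g <- array(FALSE, c(3, 3, 1))
  g[1, 1, 1] <- TRUE; g[2, 2, 1] <- TRUE
  expect_equal(label_components(g, 6)$n_components, 2L)
  expect_equal(label_components(g, 26)$n_components, 1L)
  expect_equal(label_components(array(FALSE, c(3, 3, 3)))$n_components, 0L)
})

test_that("labeling agrees with a brute-force flood fill on random grids", {
  set.seed(33)
  for (rep in 1:25) {
    m <- array(runif(512) < runif(1, 0.2, 0.7), c(8, 8, 8))
    for (conn in c(6, 26)) {
      lv <- label_components(m, conn)
      oracle <- flood_fill_labels(m, conn)
      expect_equal(lv$n_components, max(oracle))
      expect_true(same_partition(lv$labels, oracle))
    }
  }
})

test_that("labels are ordered by component size", {
  m <- array(FALSE, c(10, 10, 3))
  m[1:2, 1:2, 1] <- TRUE        # 4 voxels, first in scan order
  m[6:9, 6:9, 1:2] <- TRUE      # 32 voxels
  lv <- label_components(m)
  expect_equal(lv$sizes, c(32L, 4L))
  expect_equal(unique(as.vector(lv$labels[6:9, 6:9, 1:2])), 1L)
  expect_equal(unique(as.vector(lv$labels[1:2, 1:2, 1])), 2L)
})

test_that("component selection supports explicit, seed, and automatic modes", {
  ph <- phantom_small()
  lab <- label_components(threshold_mask(ph$volume))
  ctr <- which(ph$truth$mask, arr.ind = TRUE)
  seed_vox <- ctr[which.max(ctr[, 3] - abs(ctr[, 1] - 32)), ]
  by_seed <- select_lung_component(lab, seed = seed_vox)
  auto <- select_lung_component(lab)
  expect_equal(by_seed, auto)
  expect_equal(select_lung_component(lab, label = auto), auto)
  expect_error(select_lung_component(lab, label = lab$n_components + 1L),
               "selection error")
  bg <- which(lab$labels == 0L, arr.ind = TRUE)[1, ]
  expect_error(select_lung_component(lab, seed = bg), "background")
})

test_that("automatic selection fails gracefully on an all-air volume", {
  v <- ct_volume(array(-1000, c(16, 16, 16)))
  expect_error(segment_lung(v), "no interior component")
})

test_that("erosion of a solid cube leaves the interior core", {
  m <- array(FALSE, c(7, 7, 7)); m[2:6, 2:6, 2:6] <- TRUE
  core <- refine_mask(m, erode_radius = 1, dilate_radius = 0)
  expect_equal(sum(core), 27L)
  expect_true(all(core[3:5, 3:5, 3:5]))
})

test_that("hole filling closes an enclosed 2D cavity", {
  ring <- array(FALSE, c(7, 7, 1))
  ring[2:6, 2:6, 1] <- TRUE
  ring[3:5, 3:5, 1] <- FALSE
  filled <- refine_mask(ring, erode_radius = 0, dilate_radius = 0)
  expect_equal(sum(filled), 25L)
})

test_that("opening is anti-extensive: dilate(erode(X)) is a subset of X", {
  sphere <- array(FALSE, c(15, 15, 15))
  idx <- as.matrix(expand.grid(1:15, 1:15, 1:15))
  sphere[idx[rowSums((idx - 8)^2) <= 36, ]] <- TRUE
  for (r in 1:2) {
    opened <- refine_mask(sphere, erode_radius = r, dilate_radius = r)
    expect_true(all(sphere[opened]))
  }
})

test_that("refinement reports the stage that emptied the mask", {
  tiny <- array(FALSE, c(5, 5, 5)); tiny[3, 3, 3] <- TRUE
  expect_error(refine_mask(tiny, erode_radius = 1), "'erode' emptied")
  expect_error(refine_mask(tiny, erode_radius = -1), "parameter error")
})

test_that("base-slice cropping removes everything below the base", {
  m <- array(FALSE, c(4, 4, 60))
  m[2:3, 2:3, 10:50] <- TRUE
  lm <- crop_from_base(m, base_slice = 20, extent = "to_apex")
  occ <- which(apply(lm$mask, 3, any))
  expect_equal(range(occ), c(20L, 50L))
  expect_equal(lm$base_slice, 20L)
  ident <- crop_from_base(m, base_slice = 1)
  expect_identical(ident$mask, m)
  expect_error(crop_from_base(m, base_slice = 61), "outside stack")
  expect_error(crop_from_base(m, base_slice = 0), "outside stack")
})

test_that("the decoy blob below the lung base is cropped away", {
  ph <- phantom_default()
  seg_full <- segment_lung(ph$volume, base_slice = 1L, extent = "full_stack")
  seg_crop <- segmented_default()
  below <- seq_len(ph$base_slice - 1L)
  expect_gt(sum(seg_full$mask[, , below]), 0)        # decoy + tube present
  expect_equal(sum(seg_crop$mask[, , below]), 0L)    # removed by the crop
  above <- ph$base_slice:ph$truth$dims[3]
  expect_identical(seg_crop$mask[, , above], seg_full$mask[, , above])
})

test_that("the full pipeline is deterministic", {
  ph <- phantom_small()
  a <- segment_lung(ph$volume, base_slice = ph$base_slice)
  b <- segment_lung(ph$volume, base_slice = ph$base_slice)
  expect_identical(a$mask, b$mask)
  expect_identical(a$selected_label, b$selected_label)
})

test_that("phantom lung is recovered on the small grid too", {
  ph <- phantom_small()
  seg <- segment_lung(ph$volume, base_slice = ph$base_slice)
  rec <- mask_volume_mm3(seg)
  expect_lt(abs(rec - ph$true_volume_mm3) / ph$true_volume_mm3, 0.10)
  expect_gt(dice_coef(seg$mask, ph$truth$mask), 0.9)
})
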