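#' Per-bin measurement of a masked volume
#'
#' Segments the HU volume by bin inside the lung mask and measures each bin:
#' voxel count, volume in mm^3 (`count * spacing_x * spacing_y * spacing_z`)
#' and fraction of the total masked voxel count. One row per bin, plus an
#' `OUT_OF_RANGE` row for masked voxels outside the scheme (so counts are
#' conserved), plus a `TOTAL` row summing the in-range bins.
#'
#' @param volume a [ct_volume()].
#' @param mask a [lung_mask()] or logical array of matching dims.
#' @param scheme an [hu_bin_scheme()].
#' @param volume_id identifier written into the table.
#' @return a `measurement_table` data frame with columns
#'   `volume_id, slice, bin_label, voxel_count, measure_mm, fraction`
#'   (`slice = "ALL"`, `measure_mm` in mm^3).
#' @export
measure_bins <- function(volume, mask, scheme = hu_bin_scheme("default"),
                         volume_id = "volume") {
  volume <- as_ct_volume(volume)
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  stop_if_dim_mismatch(volume, dim(m))
  counts <- bin_counts(volume$voxels[m], scheme)
  build_measurement_table(counts, scheme, volume_id, slice = "ALL",
                          unit_measure = voxel_volume_mm3(volume))
}

bin_counts <- function(values, scheme) {
  idx <- assign_bins(values, scheme)
  nb <- n_bins(scheme)
  c(tabulate(idx, nbins = nb), sum(idx == 0L))  # bins then OUT_OF_RANGE
}

build_measurement_table <- function(counts, scheme, volume_id, slice,
                                    unit_measure) {
  nb <- n_bins(scheme)
  total <- sum(counts)
  labels <- c(scheme$labels, OUT_OF_RANGE)
  frac <- if (total > 0) counts / total else rep(0, nb + 1L)
  tab <- data.frame(
    volume_id = volume_id,
    slice = as.character(slice),
    bin_label = c(labels, "TOTAL"),
    voxel_count = c(counts, sum(counts[seq_len(nb)])),
    measure_mm = c(counts, sum(counts[seq_len(nb)])) * unit_measure,
    fraction = c(frac, sum(frac[seq_len(nb)])),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("measurement_table", "data.frame")
  tab
}

#' Total lung tissue volume from a measurement table
#'
#' Sums the per-bin volumes over the in-range bins; `OUT_OF_RANGE` and
#' `TOTAL` rows are excluded. For per-slice (mm^2) tables the sum is an area.
#'
#' @param table a `measurement_table`.
#' @return total in mm^3 (or mm^2 for slice tables).
#' @export
total_tissue_volume <- function(table) {
  stopifnot(is.data.frame(table))
  keep <- !(table$bin_label %in% c(OUT_OF_RANGE, "TOTAL"))
  sum(table$measure_mm[keep])
}

#' Per-slice region of interest
#'
#' A 2D binary mask on one slice, as drawn by an analyst during the
#' semi-manual workflow (the interactive wand selection reduced to its
#' resulting mask).
#'
#' @param slice_index 1-based slice index.
#' @param mask2d logical matrix matching the volume's in-plane dims.
#' @param analyst_id who drew it.
#' @return object of class `slice_roi`.
#' @export
slice_roi <- function(slice_index, mask2d, analyst_id = "analyst") {
  if (!is.matrix(mask2d)) stop("mask2d must be a matrix", call. = FALSE)
  storage.mode(mask2d) <- "logical"
  structure(list(slice_index = as.integer(slice_index), mask2d = mask2d,
                 analyst_id = as.character(analyst_id)),
            class = "slice_roi")
}

#' Build a slice ROI from a polygon
#'
#' Rasterizes a closed polygon (vertices in 1-based voxel coordinates) onto
#' the in-plane grid with the even-odd rule: a pixel center is inside when a
#' ray from it crosses the polygon boundary an odd number of times.
#'
#' @param slice_index 1-based slice index.
#' @param vertices two-column matrix (x, y) of polygon vertices.
#' @param dims in-plane dims `c(nx, ny)`.
#' @param analyst_id who drew it.
#' @return a [slice_roi()].
#' @export
roi_from_polygon <- function(slice_index, vertices, dims,
                             analyst_id = "analyst") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("vertices must be an n x 2 matrix with n >= 3", call. = FALSE)
  nx <- dims[1L]; ny <- dims[2L]
  px <- rep(seq_len(nx), times = ny)
  py <- rep(seq_len(ny), each = nx)
  n <- nrow(vertices)
  inside <- rep(FALSE, nx * ny)
  j <- n
  for (i in seq_len(n)) {     # even-odd crossing count
    xi <- vertices[i, 1L]; yi <- vertices[i, 2L]
    xj <- vertices[j, 1L]; yj <- vertices[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  slice_roi(slice_index, matrix(inside, nx, ny), analyst_id)
}

#' Per-bin measurement of one slice ROI
#'
#' Quantifies the voxels of one slice inside a 2D ROI: per-bin voxel (pixel)
#' counts, areas in mm^2 (`count * spacing_x * spacing_y`), and fraction of
#' the ROI's pixel count, with the same `OUT_OF_RANGE` and `TOTAL` rows as
#' [measure_bins()].
#'
#' @param volume a [ct_volume()].
#' @param roi a [slice_roi()].
#' @param scheme an [hu_bin_scheme()].
#' @param volume_id identifier written into the table.
#' @return a `measurement_table` (`measure_mm` in mm^2; `slice` = the ROI's
#'   slice index).
#' @export
measure_slice_roi <- function(volume, roi, scheme = hu_bin_scheme("default"),
                              volume_id = "volume") {
  volume <- as_ct_volume(volume)
  stopifnot(inherits(roi, "slice_roi"))
  nz <- volume$dims[3L]
  if (roi$slice_index < 1L || roi$slice_index > nz)
    stop("parameter error: ROI slice ", roi$slice_index,
         " outside stack (1..", nz, ")", call. = FALSE)
  if (!identical(dim(roi$mask2d), as.integer(volume$dims[1:2])))
    stop("geometry error: ROI dims do not match volume in-plane dims",
         call. = FALSE)
  values <- volume$voxels[, , roi$slice_index][roi$mask2d]
  counts <- bin_counts(values, scheme)
  build_measurement_table(counts, scheme, volume_id,
                          slice = roi$slice_index,
                          unit_measure = pixel_area_mm2(volume))
}

#' Offset-slice augmentation of a manual ROI
#'
#' Re-anchors a manually drawn ROI at neighboring slices to augment the
#' measuring power of each manual segmentation: by default the ROI is applied
#' to the two additional slices offset by -5 and +5. The original ROI is not
#' included in the returned list; offsets that fall outside the stack are
#' dropped with a warning.
#'
#' @param roi a [slice_roi()].
#' @param offsets integer slice offsets (default `c(-5, 5)`).
#' @param n_slices number of slices in the stack.
#' @return list of [slice_roi()] at the surviving offset slices.
#' @export
augment_roi <- function(roi, offsets = c(-5L, 5L), n_slices) {
  stopifnot(inherits(roi, "slice_roi"))
  if (length(offsets) == 0L) return(list())
  target <- roi$slice_index + as.integer(offsets)
  keep <- target >= 1L & target <= n_slices
  if (any(!keep))
    warning(sprintf("dropped %d offset slice(s) outside stack 1..%d",
                    sum(!keep), n_slices), call. = FALSE)
  lapply(target[keep], function(s)
    slice_roi(s, roi$mask2d, roi$analyst_id))
}
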