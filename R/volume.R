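#' CT volume container
#'
#' Holds a 3D grid of Hounsfield-unit (HU) voxel values together with the
#' voxel spacing and axis convention. The third array axis is the slice (z)
#' axis; slice 1 is the base (inferior, diaphragm-side) end and slice indices
#' increase toward the apex, so analysis proceeds base-to-apex in increasing
#' slice order.
#'
#' Values below -1024 HU are legal (deep-air padding, e.g. the int16 minimum
#' -32768 used as a sentinel on some scanners) but are flagged with a warning
#' when the volume is constructed.
#'
#' @param voxels numeric 3D array of HU values.
#' @param spacing numeric length-3 voxel edge lengths in mm, all > 0. A single
#'   value is recycled (isotropic).
#' @param source provenance string (file path and format, or "memory").
#' @return An object of class `ct_volume` with elements `voxels`, `spacing`,
#'   `dims`, `axis_convention` and `source`.
#' @examples
#' v <- ct_volume(array(-1000, c(4, 4, 2)), spacing = 0.107)
#' v$dims
#' @export
ct_volume <- function(voxels, spacing = 0.107, source = "memory") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array", call. = FALSE)
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels)))
    stop("voxel values must be finite", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive voxel edge lengths (mm)",
         call. = FALSE)
  if (any(voxels < -1024))
    warning("volume contains values below -1024 HU (padding/sentinel?)",
            call. = FALSE)
  structure(list(
    voxels = voxels,
    spacing = spacing,
    dims = dim(voxels),
    axis_convention = list(z_axis = 3L, z_direction = "base_to_apex"),
    source = as.character(source)[1L]
  ), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("ct_volume:", paste(x$dims, collapse = " x "), "voxels\n")
  cat("  spacing (mm):", paste(format(x$spacing), collapse = " x "), "\n")
  cat("  HU range:", paste(format(range(x$voxels)), collapse = " .. "), "\n")
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) x$dims

as_ct_volume <- function(x, spacing = 0.107, source = "memory") {
  if (inherits(x, "ct_volume")) x else ct_volume(x, spacing, source)
}

# voxel volume (mm^3) and in-plane pixel area (mm^2)
voxel_volume_mm3 <- function(x) prod(x$spacing)
pixel_area_mm2 <- function(x) x$spacing[1L] * x$spacing[2L]

stop_if_dim_mismatch <- function(volume, mask_dims, what = "mask") {
  if (!identical(as.integer(volume$dims), as.integer(mask_dims)))
    stop(sprintf("geometry error: %s dims (%s) do not match volume dims (%s)",
                 what, paste(mask_dims, collapse = "x"),
                 paste(volume$dims, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}
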