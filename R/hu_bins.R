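#' Hounsfield-unit bin schemes
#'
#' Constructs one of the three radiodensity bin schemes used for lung
#' quantification. `"default"` is the six-bin partition of \[-1000, 0\] HU
#' historically used for manual lung grading; `"mod"` splits the aerated
#' \[-1000, -500\] range into three sub-ranges (\[-1000, -700\), \[-700, -600\),
#' \[-600, -500\)) for finer discrimination of air-dominated tissue; `"range"`
#' builds uniform bins of a user-chosen width between `min_hu` and `max_hu`.
#'
#' All bins are half-open `[lo, hi)` except the last, which is closed at its
#' upper edge, so the printed edge lists form a true partition and boundary
#' voxels are counted exactly once.
#'
#' @param mode one of `"default"`, `"mod"`, `"range"`.
#' @param min_hu,max_hu,width range-mode parameters (HU); `width > 0`,
#'   `min_hu < max_hu`. The final bin is truncated (with a warning) when
#'   `width` does not divide the span.
#' @return An object of class `hu_bin_scheme` with elements `mode`, `edges`
#'   (strictly increasing HU boundaries) and `labels`.
#' @examples
#' hu_bin_scheme("default")$edges
#' hu_bin_scheme("range", min_hu = -1000, max_hu = 0, width = 500)$edges
#' @export
hu_bin_scheme <- function(mode = c("default", "mod", "range"),
                          min_hu = NULL, max_hu = NULL, width = NULL) {
  mode <- match.arg(mode)
  if (mode != "range" && (!is.null(min_hu) || !is.null(max_hu) || !is.null(width)))
    stop("parameter error: min_hu/max_hu/width only apply to mode = \"range\"",
         call. = FALSE)
  if (mode == "default") {
    edges <- c(-1000, -600, -500, -400, -300, -200, 0)
  } else if (mode == "mod") {
    edges <- c(-1000, -700, -600, -500, -400, -300, -200, 0)
  } else {
    if (is.null(min_hu) || is.null(max_hu) || is.null(width))
      stop("parameter error: range mode requires min_hu, max_hu and width",
           call. = FALSE)
    if (!is.numeric(width) || width <= 0)
      stop("parameter error: width must be > 0", call. = FALSE)
    if (min_hu >= max_hu)
      stop("parameter error: min_hu must be < max_hu", call. = FALSE)
    edges <- seq(min_hu, max_hu, by = width)
    if (edges[length(edges)] < max_hu) {
      warning(sprintf("bin width %g does not divide [%g, %g]; final bin truncated at %g",
                      width, min_hu, max_hu, max_hu), call. = FALSE)
      edges <- c(edges, max_hu)
    }
  }
  new_bin_scheme(mode, edges)
}

new_bin_scheme <- function(mode, edges) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing with at least 2 values", call. = FALSE)
  nb <- length(edges) - 1L
  close_ch <- c(rep(")", nb - 1L), "]")
  labels <- sprintf("[%g,%g%s", edges[-length(edges)], edges[-1L], close_ch)
  structure(list(mode = mode, edges = edges, labels = labels),
            class = "hu_bin_scheme")
}

#' @export
print.hu_bin_scheme <- function(x, ...) {
  cat("hu_bin_scheme (mode =", x$mode, "):",
      length(x$labels), "bins\n  ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

n_bins <- function(scheme) length(scheme$labels)

#' Label used for voxels falling outside every bin of a scheme.
#' @export
OUT_OF_RANGE <- "OUT_OF_RANGE"

#' Assign voxels to HU bins
#'
#' Maps each voxel to its bin index: voxel with value `h` gets index `i` when
#' `edges[i] <= h < edges[i+1]`; the last bin additionally owns its upper
#' edge. Voxels outside the scheme's range get index 0 (out of range).
#'
#' @param x a `ct_volume`, or any numeric array/vector of HU values.
#' @param scheme an [hu_bin_scheme()].
#' @return integer array (same shape as input): bin index in
#'   `1..n_bins`, or 0 for out-of-range voxels.
#' @examples
#' assign_bins(c(-650, -500, 0, 400), hu_bin_scheme("default"))
#' @export
assign_bins <- function(x, scheme) {
  stopifnot(inherits(scheme, "hu_bin_scheme"))
  h <- if (inherits(x, "ct_volume")) x$voxels else x
  e <- scheme$edges
  idx <- findInterval(h, e, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx == length(e)] <- 0L           # above the top edge
  idx[h < e[1L]] <- 0L
  out <- as.integer(idx)
  if (!is.null(dim(h))) dim(out) <- dim(h)
  out
}

#' Two-point HU calibration model
#'
#' Linear radiodensity calibration with air and water as reference materials:
#' `air_hu` maps to 100% air content and `water_hu` to 0% air (pure
#' water-equivalent tissue).
#'
#' @param air_hu HU of the air reference (default -1000).
#' @param water_hu HU of the water reference (default 0).
#' @return An object of class `hu_calibration`.
#' @export
hu_calibration <- function(air_hu = -1000, water_hu = 0) {
  if (!(air_hu < water_hu))
    stop("air_hu must be below water_hu", call. = FALSE)
  structure(list(air_hu = air_hu, water_hu = water_hu),
            class = "hu_calibration")
}

#' Percent air fraction of a voxel
#'
#' Affine air/tissue mixture model implied by two-point calibration: a voxel
#' at the air reference is 100% air, at the water reference 0% air, and
#' -500 HU (under the default calibration) is a 50/50 air/tissue mixture.
#' Values outside the reference interval are clamped to it, with a warning.
#'
#' @param hu numeric HU value(s).
#' @param cal an [hu_calibration()].
#' @return percent air in \[0, 100\], same shape as `hu`.
#' @examples
#' air_fraction(-500)  # 50
#' @export
air_fraction <- function(hu, cal = hu_calibration()) {
  stopifnot(inherits(cal, "hu_calibration"))
  if (any(hu < cal$air_hu | hu > cal$water_hu))
    warning("HU values outside [air_hu, water_hu] clamped before mapping",
            call. = FALSE)
  h <- pmin(pmax(hu, cal$air_hu), cal$water_hu)
  100 * (cal$water_hu - h) / (cal$water_hu - cal$air_hu)
}

#' Serialize / deserialize a bin scheme as JSON
#'
#' @param scheme an [hu_bin_scheme()].
#' @param path file path for the JSON config.
#' @return `read_bin_scheme` returns an `hu_bin_scheme`.
#' @export
write_bin_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "hu_bin_scheme"))
  jsonlite::write_json(list(mode = scheme$mode, edges = scheme$edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bin_scheme
#' @export
read_bin_scheme <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$mode) || is.null(cfg$edges))
    stop("bin scheme config must contain 'mode' and 'edges'", call. = FALSE)
  new_bin_scheme(cfg$mode, cfg$edges)
}
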