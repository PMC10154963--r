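#' Rough HU threshold mask
#'
#' Selects voxels whose HU value lies in the closed interval `[lo, hi]`. The
#' defaults (`-32768` to `-200` HU) approximate lung tissue density: the
#' lower bound is the int16 minimum so deep-air/padding values are kept, the
#' upper bound excludes soft tissue denser than connective tissue.
#'
#' @param volume a [ct_volume()] (or numeric 3D array).
#' @param lo,hi inclusive HU bounds, `lo <= hi`.
#' @return logical array of the volume's dims.
#' @export
threshold_mask <- function(volume, lo = -32768, hi = -200) {
  if (lo > hi) stop("parameter error: lo must be <= hi", call. = FALSE)
  v <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  v >= lo & v <= hi
}

#' 3D connected-component labeling
#'
#' Labels the connected components of a binary 3D mask under face (6) or
#' face+edge+corner (26) adjacency. Labels are consecutive integers
#' `1..n_components`, ordered by descending voxel count; ties are broken by
#' the component whose first voxel comes earliest in column-major scan order
#' (i.e. the lexicographically smallest (z, y, x) first-voxel coordinate).
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (default) or 26.
#' @return An object of class `labeled_volume`: `labels` (integer array,
#'   0 = background), `n_components`, `sizes` (voxels per label),
#'   `connectivity`.
#' @export
label_components <- function(mask, connectivity = 6) {
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26", call. = FALSE)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  storage.mode(mask) <- "logical"
  raw <- .cc_label3d(as.vector(mask), as.integer(dim(mask)),
                     as.integer(connectivity))
  n <- attr(raw, "n_components")
  if (n > 0L) {
    sizes <- tabulate(raw, nbins = n)
    # stable order: descending size, scan-order (= raw label) tie-break
    perm <- order(-sizes, seq_len(n))
    relab <- integer(n)
    relab[perm] <- seq_len(n)
    labels <- array(c(0L, relab)[raw + 1L], dim(mask))
    sizes <- sizes[perm]
  } else {
    labels <- array(0L, dim(mask))
    sizes <- integer(0)
  }
  structure(list(labels = labels, n_components = as.integer(n),
                 sizes = sizes, connectivity = connectivity),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("labeled_volume:", x$n_components, "components (connectivity",
      x$connectivity, ")\n")
  if (x$n_components > 0)
    cat("  sizes:", paste(utils::head(x$sizes, 8), collapse = ", "),
        if (x$n_components > 8) "...\n" else "\n")
  invisible(x)
}

#' Select the lung component
#'
#' Identifies which labeled component is the lung. Three modes mirror the
#' reader's verification step non-interactively:
#' * `label`: the reader already knows the component index.
#' * `seed`: a voxel coordinate known to lie inside the lung; its label is
#'   returned.
#' * automatic (default, neither given): the largest component that does not
#'   touch the volume boundary on 4 or more of the 6 faces. This excludes
#'   the exterior-air component, which wraps the animal and touches all
#'   faces; ties go to the lowest label.
#'
#' @param labeled a `labeled_volume` from [label_components()].
#' @param label explicit component label (positive integer).
#' @param seed integer voxel coordinate `c(x, y, z)` (1-based).
#' @return the selected label (integer).
#' @export
select_lung_component <- function(labeled, label = NULL, seed = NULL) {
  stopifnot(inherits(labeled, "labeled_volume"))
  if (labeled$n_components == 0L)
    stop("selection error: mask has no components", call. = FALSE)
  if (!is.null(label)) {
    label <- as.integer(label)
    if (length(label) != 1L || label < 1L || label > labeled$n_components)
      stop("selection error: label ", label, " not present (components: 1..",
           labeled$n_components, ")", call. = FALSE)
    return(label)
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    d <- dim(labeled$labels)
    if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
      stop("selection error: seed voxel outside volume", call. = FALSE)
    lab <- labeled$labels[seed[1L], seed[2L], seed[3L]]
    if (lab == 0L)
      stop("selection error: seed voxel is background", call. = FALSE)
    return(lab)
  }
  # automatic: largest component touching < 4 of the 6 volume faces
  d <- dim(labeled$labels)
  faces_touched <- integer(labeled$n_components)
  face_labels <- list(
    labeled$labels[1L, , ], labeled$labels[d[1L], , ],
    labeled$labels[, 1L, ], labeled$labels[, d[2L], ],
    labeled$labels[, , 1L], labeled$labels[, , d[3L]]
  )
  for (f in face_labels) {
    present <- unique(as.vector(f))
    present <- present[present > 0L]
    faces_touched[present] <- faces_touched[present] + 1L
  }
  interior <- which(faces_touched < 4L)
  if (length(interior) == 0L)
    stop("selection error: no interior component found; supply seed= or label=",
         call. = FALSE)
  interior[which.max(labeled$sizes[interior])]  # labels are size-ordered;
}                                               # which.max takes the first tie

#' Morphological refinement of a component mask
#'
#' Cleans the selected component: (1) erosion with the 3D 6-neighborhood
#' structuring element (`erode_radius` iterations) smooths the edges and
#' severs thin bridges such as the trachea/esophagus; (2) slice-wise 2D hole
#' filling closes enclosed low-density gaps (vessels, partial-volume holes);
#' (3) dilation (`dilate_radius` iterations) re-includes the pleural rim of
#' connective tissue around the lung.
#'
#' @param mask logical 3D array (the selected component).
#' @param erode_radius,dilate_radius non-negative iteration counts
#'   (defaults 2 and 1, balanced on the phantom so the refined boundary
#'   tracks the true lung surface).
#' @param verbose log before/after voxel counts per stage.
#' @return refined logical array.
#' @export
refine_mask <- function(mask, erode_radius = 2, dilate_radius = 1,
                        verbose = FALSE) {
  if (erode_radius < 0 || dilate_radius < 0)
    stop("parameter error: radii must be >= 0", call. = FALSE)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  storage.mode(mask) <- "logical"
  d <- as.integer(dim(mask))
  stage <- function(m, name) {
    if (!any(m))
      stop("refinement error: stage '", name, "' emptied the mask",
           call. = FALSE)
    if (verbose) message(sprintf("  refine[%s]: %d voxels", name, sum(m)))
    m
  }
  m <- stage(mask, "input")
  if (erode_radius > 0)
    m <- stage(array(.morph3d(as.vector(m), d, as.integer(erode_radius),
                              TRUE, TRUE), d), "erode")
  m <- stage(array(.fill_holes2d(as.vector(m), d), d), "fill")
  if (dilate_radius > 0)
    m <- stage(array(.morph3d(as.vector(m), d, as.integer(dilate_radius),
                              FALSE, TRUE), d), "dilate")
  m
}

#' Lung mask container
#'
#' Binary 3D lung segmentation plus the provenance of how it was produced:
#' which component was selected, the base slice bounding the analysis, and
#' the refinement parameters.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing in mm (length 3).
#' @param selected_label component label the mask came from (NA for e.g.
#'   phantom ground truth).
#' @param base_slice inclusive lower slice bound of the analyzed range.
#' @param refine_params named list (erode_radius, fill, dilate_radius).
#' @return object of class `lung_mask`.
#' @export
lung_mask <- function(mask, spacing = 0.107, selected_label = NA_integer_,
                      base_slice = 1L, refine_params = list()) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(mask = mask, dims = dim(mask), spacing = as.numeric(spacing),
                 selected_label = as.integer(selected_label),
                 base_slice = as.integer(base_slice),
                 refine_params = refine_params),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat("lung_mask:", sum(x$mask), "voxels in",
      paste(x$dims, collapse = " x "), "grid\n")
  cat("  volume:", format(mask_volume_mm3(x)), "mm^3; base slice:",
      x$base_slice, "; label:", x$selected_label, "\n")
  invisible(x)
}

#' Total mask volume in mm^3
#' @param mask a [lung_mask()].
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "lung_mask"))
  sum(mask$mask) * prod(mask$spacing)
}

#' Crop a mask at the base of the lung
#'
#' The reader identifies the bottom (base) of the lung in the slice stack;
#' analysis then proceeds from the base toward the apex. All slices below
#' `base_slice` (slice indices `< base_slice`; slice 1 is the inferior end)
#' are zeroed, removing sub-diaphragm structures such as bowel gas. With
#' `extent = "to_apex"` the retained range ends at the last non-empty slice;
#' `"full_stack"` keeps everything above the base (e.g. up to the sinus
#' cavity).
#'
#' @param mask logical 3D array or `lung_mask`.
#' @param base_slice 1-based slice index, within the stack.
#' @param extent `"to_apex"` or `"full_stack"`.
#' @param spacing,selected_label,refine_params provenance carried into the
#'   returned object (ignored when `mask` is already a `lung_mask`).
#' @return a [lung_mask()] with `base_slice` recorded.
#' @export
crop_from_base <- function(mask, base_slice, extent = c("to_apex", "full_stack"),
                           spacing = 0.107, selected_label = NA_integer_,
                           refine_params = list()) {
  extent <- match.arg(extent)
  if (inherits(mask, "lung_mask")) {
    spacing <- mask$spacing
    selected_label <- mask$selected_label
    refine_params <- mask$refine_params
    mask <- mask$mask
  }
  nz <- dim(mask)[3L]
  base_slice <- as.integer(base_slice)
  if (length(base_slice) != 1L || base_slice < 1L || base_slice > nz)
    stop("parameter error: base_slice outside stack (1..", nz, ")",
         call. = FALSE)
  m <- mask
  if (base_slice > 1L) m[, , seq_len(base_slice - 1L)] <- FALSE
  if (extent == "to_apex") {
    occ <- which(apply(m, 3L, any))
    if (length(occ) > 0 && max(occ) < nz)
      m[, , seq(max(occ) + 1L, nz)] <- FALSE  # no-op; above-apex already empty
  }
  lung_mask(m, spacing = spacing, selected_label = selected_label,
            base_slice = base_slice, refine_params = refine_params)
}

#' Full semi-automated lung segmentation
#'
#' Deterministic composition of the pipeline stages:
#' [threshold_mask()] with `[lo, hi]` -> [label_components()] ->
#' [select_lung_component()] -> [refine_mask()] -> [crop_from_base()].
#' Given identical inputs and parameters the result is bitwise identical;
#' the only reader inputs are the component choice (or automatic selection)
#' and the base slice.
#'
#' @param volume a [ct_volume()].
#' @param lo,hi threshold bounds in HU (defaults -32768, -200).
#' @param connectivity 6 or 26 for component labeling.
#' @param label,seed component selection (see [select_lung_component()]);
#'   both `NULL` selects automatically.
#' @param base_slice inclusive base-of-lung slice (default 1 = keep all).
#' @param extent `"to_apex"` or `"full_stack"`.
#' @param erode_radius,dilate_radius refinement iterations (defaults 2, 1).
#' @param verbose log intermediate voxel counts.
#' @return a [lung_mask()].
#' @export
segment_lung <- function(volume, lo = -32768, hi = -200, connectivity = 6,
                         label = NULL, seed = NULL, base_slice = 1L,
                         extent = c("to_apex", "full_stack"),
                         erode_radius = 2, dilate_radius = 1,
                         verbose = FALSE) {
  volume <- as_ct_volume(volume)
  extent <- match.arg(extent)
  thr <- threshold_mask(volume, lo, hi)
  if (verbose) message("threshold: ", sum(thr), " voxels")
  lab <- label_components(thr, connectivity)
  if (verbose) message("components: ", lab$n_components)
  sel <- select_lung_component(lab, label = label, seed = seed)
  comp <- lab$labels == sel
  if (verbose) message("selected label ", sel, ": ", sum(comp), " voxels")
  ref <- refine_mask(comp, erode_radius, dilate_radius, verbose = verbose)
  crop_from_base(ref, base_slice, extent, spacing = volume$spacing,
                 selected_label = sel,
                 refine_params = list(erode_radius = erode_radius,
                                      fill = "slice2d",
                                      dilate_radius = dilate_radius))
}
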