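#' Synthetic mouse-thorax phantom specification
#'
#' Describes a synthetic micro-CT volume with exact ground truth: an
#' ellipsoidal body with a dense chest wall, two ellipsoidal lung lobes with
#' embedded cylindrical airways joined by a carina/main-bronchi bridge (so
#' the lung is a single connected component, as the pipeline expects), a
#' spherical heart notch carved between the
#' lobes, and (optionally) a sub-diaphragm gas "decoy" blob connected to the
#' lung base through a thin airway tube — present specifically so base-slice
#' cropping has something to remove. Default grid is 128 x 128 x 192 at
#' 0.107 mm isotropic, a quarter-linear-scale analog of a 512 x 512 x 768
#' scanner reconstruction.
#'
#' Tissue classes (HU mean, SD): exterior air (-1000, 10); lung parenchyma
#' (-650, 120, clipped to \[-1000, -300\]); airway lumen (-950, 20);
#' heart/connective tissue (-100, 60); chest wall/bone (+300, 150). After
#' class assignment, independent Gaussian noise is added per voxel and the
#' volume is blurred with a Gaussian of `blur_sigma` voxels to emulate
#' partial-volume averaging.
#'
#' The `"fibrotic"` preset emulates the dense, shrunken lung of bleomycin
#' injury: parenchyma mean shifted from -650 to -450 HU (clip \[-1000, -250\])
#' and lung axes shrunk by 15%.
#'
#' @param preset `"default"` or `"fibrotic"`.
#' @param dims voxel counts per axis (>= 32 each).
#' @param spacing isotropic voxel edge (mm) or length-3 vector.
#' @param blur_sigma Gaussian partial-volume blur, in voxels.
#' @param noise multiplier on all tissue SDs (0 = noiseless class means).
#' @param decoy include the sub-base decoy blob and its connecting tube.
#' @param seed RNG seed making generation deterministic.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(preset = c("default", "fibrotic"),
                         dims = c(128L, 128L, 192L), spacing = 0.107,
                         blur_sigma = 0.7, noise = 1, decoy = TRUE,
                         seed = 42L) {
  preset <- match.arg(preset)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 32L))
    stop("parameter error: dims must be three values >= 32", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  tissues <- data.frame(
    name = c("exterior_air", "parenchyma", "airway", "heart_connective",
             "wall_bone"),
    mean = c(-1000, -650, -950, -100, 300),
    sd = c(10, 120, 20, 60, 150) * noise,
    clip_lo = c(-Inf, -1000, -Inf, -Inf, -Inf),
    clip_hi = c(Inf, -300, Inf, Inf, Inf),
    stringsAsFactors = FALSE
  )
  lung_scale <- 1
  if (preset == "fibrotic") {
    tissues$mean[tissues$name == "parenchyma"] <- -450
    tissues$clip_hi[tissues$name == "parenchyma"] <- -250
    lung_scale <- 0.85
  }
  structure(list(preset = preset, dims = dims, spacing = as.numeric(spacing),
                 blur_sigma = blur_sigma, noise = noise, decoy = decoy,
                 seed = as.integer(seed), tissues = tissues,
                 lung_scale = lung_scale),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# coordinate grids (1-based voxel centers) for mask geometry
ellipsoid_mask <- function(X, Y, Z, center, semi) {
  ((X - center[1L]) / semi[1L])^2 + ((Y - center[2L]) / semi[2L])^2 +
    ((Z - center[3L]) / semi[3L])^2 <= 1
}

#' Generate a synthetic thorax phantom
#'
#' Builds the HU volume described by a [phantom_spec()] together with the
#' exact ground-truth lung mask (parenchyma plus intra-lung airway, taken
#' before noise and blur) and its volume in mm^3. Generation is fully
#' deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([ct_volume()]), `truth`
#'   ([lung_mask()] ground truth), `true_volume_mm3`, `base_slice` (first
#'   slice containing lung; the decoy lies strictly below it) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(dims = c(48, 48, 64)))
#' ph$true_volume_mm3
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$dims[1L]; ny <- spec$dims[2L]; nz <- spec$dims[3L]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  X <- array(rep(seq_len(nx), times = ny * nz), spec$dims)
  Y <- array(rep(rep(seq_len(ny), each = nx), times = nz), spec$dims)
  Z <- array(rep(seq_len(nz), each = nx * ny), spec$dims)

  body_semi <- c(0.42 * nx, 0.40 * ny, 0.48 * nz)
  body_ctr <- c(cx, cy, 0.5 * nz)
  body <- ellipsoid_mask(X, Y, Z, body_ctr, body_semi)
  wall_t <- max(2, round(0.035 * nx))
  inner <- ellipsoid_mask(X, Y, Z, body_ctr, body_semi - wall_t)
  wall <- body & !inner

  lobe_semi <- c(0.125 * nx, 0.21 * ny, 0.26 * nz) * spec$lung_scale
  lobe_dx <- 0.17 * nx
  zc <- 0.55 * nz
  lung <- ellipsoid_mask(X, Y, Z, c(cx - lobe_dx, cy, zc), lobe_semi) |
          ellipsoid_mask(X, Y, Z, c(cx + lobe_dx, cy, zc), lobe_semi)
  lung <- lung & inner
  if (!any(lung))
    stop("parameter error: lung geometry does not fit the requested dims",
         call. = FALSE)

  heart <- ellipsoid_mask(X, Y, Z, c(cx, cy, 0.52 * nz), rep(0.11 * nx, 3L))
  lung <- lung & !heart

  r_air <- max(2, round(0.022 * nx))
  airway <- (((X - (cx - lobe_dx))^2 + (Y - cy)^2 <= r_air^2) |
             ((X - (cx + lobe_dx))^2 + (Y - cy)^2 <= r_air^2)) & lung
  # carina / main-bronchi bridge joining the lobes into one connected lung
  bridge <- ((Y - cy)^2 + (Z - 0.70 * nz)^2 <= r_air^2) &
    X >= cx - lobe_dx & X <= cx + lobe_dx & inner & !lung
  airway <- airway | bridge
  lung <- lung | bridge

  base_slice <- min(which(apply(lung, 3L, any)))

  decoy <- array(FALSE, spec$dims)
  tube <- array(FALSE, spec$dims)
  if (spec$decoy) {
    decoy <- ellipsoid_mask(X, Y, Z, c(cx - lobe_dx, cy, 0.12 * nz),
                            rep(0.09 * nx, 3L)) & inner
    tube <- ((X - (cx - lobe_dx))^2 + (Y - cy)^2 <= r_air^2) &
      Z >= 0.12 * nz & Z <= zc - 0.5 * lobe_semi[3L] & inner & !lung
  }

  # class index per voxel; later assignments overwrite earlier ones
  tn <- spec$tissues$name
  cls <- array(match("exterior_air", tn), spec$dims)
  cls[body] <- match("heart_connective", tn)
  cls[wall] <- match("wall_bone", tn)
  cls[lung] <- match("parenchyma", tn)
  cls[airway | tube | decoy] <- match("airway", tn)

  vox <- with_seed(spec$seed, {
    v <- array(0, spec$dims)
    for (i in seq_len(nrow(spec$tissues))) {
      sel <- cls == i
      nsel <- sum(sel)
      if (nsel == 0L) next
      val <- rep(spec$tissues$mean[i], nsel)
      if (spec$tissues$sd[i] > 0)
        val <- val + stats::rnorm(nsel, 0, spec$tissues$sd[i])
      val <- pmin(pmax(val, spec$tissues$clip_lo[i]), spec$tissues$clip_hi[i])
      v[sel] <- val
    }
    v
  })
  if (spec$blur_sigma > 0)
    vox <- array(.gauss_blur3d(as.vector(vox), spec$dims, spec$blur_sigma),
                 spec$dims)

  truth_mask <- lung  # parenchyma + intra-lung airway, pre-noise/blur
  truth <- lung_mask(truth_mask, spacing = spec$spacing,
                     base_slice = base_slice,
                     refine_params = list(ground_truth = TRUE))
  list(volume = suppressWarnings(
         ct_volume(vox, spacing = spec$spacing,
                   source = sprintf("phantom(%s, seed=%d)", spec$preset,
                                    spec$seed))),
       truth = truth,
       true_volume_mm3 = sum(truth_mask) * prod(spec$spacing),
       base_slice = base_slice,
       spec = spec)
}

#' Simulate a manual reader's slice ROI
#'
#' Perturbs one slice of the ground-truth lung mask with a random
#' morphological jitter emulating reader variability: an integer radius `r`
#' is drawn uniformly from `-reader_noise..reader_noise`; negative `r`
#' erodes the truth slice by `|r|` pixels, positive `r` dilates it
#' (4-neighborhood, in-plane), zero leaves it unchanged.
#'
#' @param truth ground-truth [lung_mask()].
#' @param slice_index slice to read; must intersect the mask.
#' @param reader_noise maximum jitter radius in pixels (0 = perfect reader).
#' @param seed RNG seed.
#' @param analyst_id identifier recorded in the ROI.
#' @return a [slice_roi()].
#' @export
simulate_manual_roi <- function(truth, slice_index, reader_noise = 1,
                                seed = 1L, analyst_id = "sim_reader") {
  stopifnot(inherits(truth, "lung_mask"))
  nz <- truth$dims[3L]
  if (slice_index < 1L || slice_index > nz)
    stop("parameter error: slice outside stack", call. = FALSE)
  m2 <- truth$mask[, , slice_index]
  if (!any(m2))
    stop("parameter error: slice ", slice_index,
         " does not intersect the lung mask", call. = FALSE)
  r <- if (reader_noise > 0) {
    with_seed(seed, sample(seq(-reader_noise, reader_noise), 1L))
  } else 0L
  if (r != 0) {
    d <- c(dim(m2), 1L)
    m2 <- array(.morph3d(as.vector(m2), as.integer(d), abs(r),
                         r < 0, FALSE), d)[, , 1L]
  }
  slice_roi(slice_index, m2, analyst_id)
}
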