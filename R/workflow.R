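#' Run the semi-automated workflow on one volume
#'
#' Composes the full pipeline on a single volume: segmentation
#' ([segment_lung()]) followed by per-bin quantification ([measure_bins()]).
#' Writes three artifacts into `out_dir`: the lung mask
#' (`<id>_mask.nii.gz`), the measurement table (`<id>_measurements.csv`) and
#' a JSON provenance sidecar (`<id>_sidecar.json`) echoing every resolved
#' parameter plus the input checksum, so any artifact can be reproduced from
#' its sidecar alone.
#'
#' @param input path to a readable volume (see [read_volume()]) or a
#'   [ct_volume()].
#' @param out_dir output directory (created if missing).
#' @param volume_id identifier for output filenames and table rows; defaults
#'   to the input's base name.
#' @param scheme an [hu_bin_scheme()] (or a mode string).
#' @param format,spacing passed to [read_volume()] when `input` is a path.
#' @param ... segmentation parameters forwarded to [segment_lung()].
#' @return invisible list with `mask`, `table` and the artifact `paths`.
#' @export
run_auto_workflow <- function(input, out_dir, volume_id = NULL,
                              scheme = hu_bin_scheme("default"),
                              format = "auto", spacing = NULL, ...) {
  if (is.character(scheme)) scheme <- hu_bin_scheme(scheme)
  if (is.character(input)) {
    if (is.null(volume_id))
      volume_id <- sub("\\.[^.]*$", "", basename(input))
    checksum <- if (file.exists(input) && !dir.exists(input))
      unname(tools::md5sum(input)) else NA_character_
    volume <- read_volume(input, format = format, spacing = spacing)
  } else {
    volume <- as_ct_volume(input)
    if (is.null(volume_id)) volume_id <- "volume"
    checksum <- NA_character_
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seg_params <- list(...)
  mask <- do.call(segment_lung, c(list(volume = volume), seg_params))
  table <- measure_bins(volume, mask, scheme, volume_id = volume_id)

  paths <- list(
    mask = file.path(out_dir, paste0(volume_id, "_mask.nii.gz")),
    table = file.path(out_dir, paste0(volume_id, "_measurements.csv")),
    sidecar = file.path(out_dir, paste0(volume_id, "_sidecar.json"))
  )
  write_mask(mask, paths$mask, format = "nifti")
  write_measurements(table, paths$table)
  sidecar <- list(
    workflow = "auto",
    volume_id = volume_id,
    input = volume$source,
    input_md5 = checksum,
    dims = volume$dims,
    spacing_mm = volume$spacing,
    bin_scheme = list(mode = scheme$mode, edges = scheme$edges),
    segmentation = utils::modifyList(
      list(lo = -32768, hi = -200, connectivity = 6, base_slice = 1,
           extent = "to_apex", erode_radius = 2, dilate_radius = 1),
      seg_params),
    selected_label = mask$selected_label,
    mask_voxels = sum(mask$mask),
    total_tissue_volume_mm3 = total_tissue_volume(table)
  )
  jsonlite::write_json(sidecar, paths$sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(mask = mask, table = table, paths = paths))
}

#' Batch-process a directory of volumes
#'
#' Applies [run_auto_workflow()] to every volume in a directory. A failure
#' on one volume is logged and does not abort the batch; the return value
#' reports per-volume success so callers (and the CLI exit status) can
#' reflect partial failure.
#'
#' @param input_dir directory containing volumes (Analyze stems, `.tif`
#'   stacks, or DICOM subdirectories).
#' @param out_dir output directory.
#' @param ... forwarded to [run_auto_workflow()].
#' @return data frame with columns `input`, `ok`, `error`.
#' @export
run_batch <- function(input_dir, out_dir, ...) {
  if (!dir.exists(input_dir))
    stop("usage error: input directory '", input_dir, "' not found",
         call. = FALSE)
  entries <- c(
    list.files(input_dir, pattern = "\\.(hdr|tif|tiff)$", full.names = TRUE,
               ignore.case = TRUE),
    list.dirs(input_dir, recursive = FALSE)
  )
  if (length(entries) == 0)
    stop("usage error: no volumes found in '", input_dir, "'", call. = FALSE)
  res <- lapply(entries, function(p) {
    out <- tryCatch({
      run_auto_workflow(p, out_dir, ...)
      list(ok = TRUE, error = NA_character_)
    }, error = function(e) {
      message("batch: '", p, "' failed: ", conditionMessage(e))
      list(ok = FALSE, error = conditionMessage(e))
    })
    data.frame(input = p, ok = out$ok, error = out$error,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
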