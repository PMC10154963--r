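#' Read a micro-CT volume
#'
#' Reads a 3D volume from one of the supported on-disk formats and normalizes
#' it into a [ct_volume()] of Hounsfield units. Integer on-disk values are
#' promoted to double without rescaling, except where the format's own
#' slope/intercept metadata dictates it (DICOM RescaleSlope/RescaleIntercept
#' are always applied).
#'
#' Formats:
#' * `analyze`: an Analyze 7.5 `.hdr`/`.img` pair (path may name either file
#'   or the common stem); voxel spacing is taken from the header `pixdim`.
#' * `dicom_dir`: a directory of single-frame CT DICOM files (explicit VR,
#'   little endian, uncompressed); slices are sorted by their z position and
#'   must agree on in-plane spacing and inter-slice step within 1%.
#' * `tiff_stack`: a multi-page TIFF; TIFF carries no spacing, so `spacing`
#'   is used (default 0.107 mm isotropic, with a warning when defaulted).
#'   Pixel values are 16-bit offset-binary: HU = stored - 32768.
#' * `auto`: guessed from the path (directory -> dicom_dir, `.tif`/`.tiff` ->
#'   tiff_stack, `.hdr`/`.img` or an existing `.hdr` sibling -> analyze).
#'
#' @param path file, stem or directory path.
#' @param format one of `"auto"`, `"analyze"`, `"dicom_dir"`, `"tiff_stack"`.
#' @param spacing voxel spacing in mm for formats that do not store it (TIFF).
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "analyze", "dicom_dir", "tiff_stack"),
                        spacing = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    analyze    = read_analyze_volume(path),
    dicom_dir  = read_dicom_dir(path),
    tiff_stack = read_tiff_stack(path, spacing)
  )
}

guess_format <- function(path) {
  if (dir.exists(path)) return("dicom_dir")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff_stack")
  if (ext %in% c("hdr", "img") || file.exists(paste0(path, ".hdr")))
    return("analyze")
  stop("format error: cannot guess format of '", path, "'", call. = FALSE)
}

## ---- Analyze 7.5 ----------------------------------------------------------

read_analyze_volume <- function(path) {
  stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
  hdr <- paste0(stem, ".hdr")
  img <- paste0(stem, ".img")
  if (!file.exists(hdr))
    stop("format error: missing Analyze header file '", hdr, "'", call. = FALSE)
  if (!file.exists(img))
    stop("format error: missing Analyze image file '", img, "'", call. = FALSE)
  a <- oro.nifti::readANALYZE(stem)
  vox <- array(as.numeric(a@.Data), dim(a@.Data)[1:3])
  sp <- a@pixdim[2:4]
  if (any(sp <= 0))
    stop("format error: Analyze header field 'pixdim' not positive", call. = FALSE)
  suppressWarnings(ct_volume(vox, spacing = sp,
                             source = paste0(stem, " (analyze)")))
}

#' Write a CT volume to disk
#'
#' Counterpart of [read_volume()], mainly used to exchange data with other
#' tools and to build test fixtures. Analyze stores float32 voxels (exact
#' round-trip); `tiff_stack` and `dicom_dir` store 16-bit integers, so
#' non-integer HU values are rounded.
#'
#' @param volume a [ct_volume()].
#' @param path output stem (analyze), file (tiff) or directory (dicom).
#' @param format one of `"analyze"`, `"dicom_dir"`, `"tiff_stack"`.
#' @param rescale_intercept,rescale_slope DICOM rescale metadata; stored
#'   values are `(HU - intercept) / slope`, rounded to integers.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path,
                         format = c("analyze", "dicom_dir", "tiff_stack"),
                         rescale_intercept = 0, rescale_slope = 1) {
  stopifnot(inherits(volume, "ct_volume"))
  format <- match.arg(format)
  switch(format,
    analyze = {
      a <- oro.nifti::anlz(volume$voxels, datatype = 16L)  # float32
      a@pixdim[2:4] <- volume$spacing
      oro.nifti::writeANALYZE(a, path, gzipped = FALSE)
    },
    tiff_stack = {
      u <- round(volume$voxels) + 32768
      if (any(u < 0 | u > 65535))
        stop("tiff_stack supports HU in [-32768, 32767] only", call. = FALSE)
      pages <- lapply(seq_len(volume$dims[3L]),
                      function(k) matrix(u[, , k] / 65535,
                                         volume$dims[1L], volume$dims[2L]))
      tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE,
                      compression = "none")
    },
    dicom_dir = write_dicom_dir(volume, path, rescale_intercept, rescale_slope)
  )
  invisible(path)
}

## ---- TIFF stacks ----------------------------------------------------------

read_tiff_stack <- function(path, spacing = NULL) {
  if (!file.exists(path))
    stop("format error: missing TIFF file '", path, "'", call. = FALSE)
  if (is.null(spacing)) {
    warning("TIFF carries no voxel spacing; defaulting to 0.107 mm isotropic",
            call. = FALSE)
    spacing <- 0.107
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  vox <- array(NA_real_, c(d[1L], d[2L], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- pages[[k]] - 32768
  suppressWarnings(ct_volume(vox, spacing = spacing,
                             source = paste0(path, " (tiff_stack)")))
}

## ---- Minimal DICOM (explicit VR little endian, uncompressed CT slices) ----
## No DICOM codec is re-implemented here beyond the element grammar needed
## for uncompressed single-frame CT: tag / VR / length / value, with the
## long-length form for OB/OW/SQ/UT/UN.

dcm_tag <- function(group, elem) {
  c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
    writeBin(as.integer(elem), raw(), size = 2, endian = "little"))
}

dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("DS", "IS", "CS", "UI", "LO", "SH")) {
    v <- charToRaw(as.character(value))
    if (length(v) %% 2 == 1)
      v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
    body <- v
  } else if (vr == "US") {
    body <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    body <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "OW") {
    body <- value  # already raw
  } else stop("unsupported VR ", vr)
  if (vr %in% c("OB", "OW", "SQ", "UT", "UN")) {
    len <- c(as.raw(c(0, 0)),
             writeBin(length(body), raw(), size = 4, endian = "little"))
  } else {
    len <- writeBin(length(body), raw(), size = 2, endian = "little")
  }
  c(dcm_tag(group, elem), charToRaw(vr), len, body)
}

write_dicom_dir <- function(volume, dir, rescale_intercept = 0, rescale_slope = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nx <- volume$dims[1L]; ny <- volume$dims[2L]; nz <- volume$dims[3L]
  sp <- volume$spacing
  for (k in seq_len(nz)) {
    stored <- round((volume$voxels[, , k] - rescale_intercept) / rescale_slope)
    if (any(stored < -32768 | stored > 32767))
      stop("stored DICOM values exceed int16 range; adjust rescale metadata",
           call. = FALSE)
    px <- writeBin(as.integer(as.vector(stored)), raw(), size = 2,
                   endian = "little")
    meta <- dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    con <- file(file.path(dir, sprintf("slice%04d.dcm", k)), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(dcm_element(0x0002, 0x0000, "UL", length(meta)), con)
    writeBin(meta, con)
    writeBin(c(
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0018, 0x0050, "DS", format(sp[3L], digits = 10)),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS",
                  paste(0, 0, format((k - 1) * sp[3L], digits = 10), sep = "\\")),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0010, "US", ny),     # Rows
      dcm_element(0x0028, 0x0011, "US", nx),     # Columns
      dcm_element(0x0028, 0x0030, "DS",
                  paste(format(sp[2L], digits = 10),
                        format(sp[1L], digits = 10), sep = "\\")),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),     # signed
      dcm_element(0x0028, 0x1052, "DS", format(rescale_intercept, digits = 10)),
      dcm_element(0x0028, 0x1053, "DS", format(rescale_slope, digits = 10)),
      dcm_element(0x7FE0, 0x0010, "OW", px)
    ), con)
    close(con)
    on.exit()
  }
  invisible(dir)
}

read_dicom_slice <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("format error: '", path, "' is not a DICOM part-10 file (missing DICM magic)",
         call. = FALSE)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  pos <- 133L
  out <- list()
  u16 <- function(p) readBin(bytes[p:(p + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(p) readBin(bytes[p:(p + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    val <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", group, elem)
    out[[key]] <- list(vr = vr, bytes = val)
    pos <- vstart + len
  }
  get_str <- function(key) {
    e <- out[[key]]
    if (is.null(e)) return(NULL)
    trimws(gsub("\\x00", "", rawToChar(e$bytes), useBytes = TRUE))
  }
  get_us <- function(key) {
    e <- out[[key]]
    if (is.null(e)) return(NULL)
    readBin(e$bytes, "integer", size = 2, endian = "little", signed = FALSE)
  }
  need <- function(x, name) {
    if (is.null(x))
      stop("format error: DICOM file '", path, "' lacks required field ", name,
           call. = FALSE)
    x
  }
  rows <- need(get_us("00280010"), "Rows")
  cols <- need(get_us("00280011"), "Columns")
  bits <- need(get_us("00280100"), "BitsAllocated")
  if (bits != 16L)
    stop("format error: only 16-bit DICOM pixel data supported", call. = FALSE)
  signed <- identical(get_us("00280103"), 1L)
  slope <- as.numeric(get_str("00281053") %||% "1")
  intercept <- as.numeric(get_str("00281052") %||% "0")
  psp <- as.numeric(strsplit(need(get_str("00280030"), "PixelSpacing"),
                             "\\\\")[[1L]])
  ipp <- get_str("00200032")
  zpos <- if (!is.null(ipp)) as.numeric(strsplit(ipp, "\\\\")[[1L]])[3L] else NA_real_
  inst <- as.numeric(get_str("00200013") %||% NA)
  thick <- as.numeric(get_str("00180050") %||% NA)
  px <- need(out[["7FE00010"]], "PixelData")$bytes
  stored <- readBin(px, "integer", n = as.integer(rows) * cols, size = 2,
                    endian = "little", signed = signed)
  hu <- stored * slope + intercept
  list(pixels = matrix(hu, nrow = cols, ncol = rows),  # x fastest
       spacing_inplane = c(psp[2L], psp[1L]), z = zpos,
       instance = inst, thickness = thick)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_dicom_dir <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0)
    stop("format error: no .dcm files in '", path, "'", call. = FALSE)
  slices <- lapply(files, read_dicom_slice)
  ord <- order(vapply(slices, function(s)
    if (is.finite(s$z)) s$z else s$instance, numeric(1)))
  slices <- slices[ord]
  sp_xy <- slices[[1L]]$spacing_inplane
  for (s in slices)
    if (any(abs(s$spacing_inplane - sp_xy) > 0.01 * sp_xy))
      stop("geometry error: inconsistent in-plane DICOM pixel spacing (>1%)",
           call. = FALSE)
  zs <- vapply(slices, `[[`, numeric(1), "z")
  if (length(slices) > 1L && all(is.finite(zs))) {
    dz <- diff(zs)
    if (any(abs(dz - dz[1L]) > 0.01 * abs(dz[1L])))
      stop("geometry error: inconsistent DICOM slice spacing (>1% deviation)",
           call. = FALSE)
    sp_z <- abs(dz[1L])
  } else {
    sp_z <- slices[[1L]]$thickness
    if (!is.finite(sp_z)) sp_z <- sp_xy[1L]
  }
  d <- dim(slices[[1L]]$pixels)
  vox <- array(NA_real_, c(d[1L], d[2L], length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$pixels
  suppressWarnings(ct_volume(vox, spacing = c(sp_xy, sp_z),
                             source = paste0(path, " (dicom_dir)")))
}

## ---- Mask export ----------------------------------------------------------

#' Write / read a binary lung mask
#'
#' Persists a segmentation mask so it can be reviewed in external viewers.
#' `nifti` stores an 8-bit NIfTI-1 volume with the mask's voxel spacing;
#' `tiff_stack` stores one bilevel page per slice (no spacing metadata).
#' Re-reading reproduces the mask voxelwise.
#'
#' @param mask a [lung_mask()] or logical 3D array.
#' @param path output file.
#' @param format `"nifti"` or `"tiff_stack"`.
#' @param spacing spacing in mm used when `mask` is a bare array (nifti only).
#' @return `path` invisibly; `read_mask` returns a logical 3D array.
#' @export
write_mask <- function(mask, path, format = c("nifti", "tiff_stack"),
                       spacing = 0.107) {
  format <- match.arg(format)
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  if (inherits(mask, "lung_mask")) spacing <- mask$spacing
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!is.array(m) || length(dim(m)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (format == "nifti") {
    im <- RNifti::asNifti(array(as.integer(m), dim(m)))
    RNifti::pixdim(im) <- spacing
    RNifti::writeNifti(im, path, datatype = "uint8")
  } else {
    pages <- lapply(seq_len(dim(m)[3L]),
                    function(k) matrix(as.numeric(m[, , k]),
                                       dim(m)[1L], dim(m)[2L]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE,
                    compression = "none")
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, format = c("nifti", "tiff_stack")) {
  format <- match.arg(format)
  if (format == "nifti") {
    im <- RNifti::readNifti(path)
    array(as.array(im) != 0, dim(im))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1L]])
    m <- array(FALSE, c(d[1L], d[2L], length(pages)))
    for (k in seq_along(pages)) m[, , k] <- pages[[k]] != 0
    m
  }
}

## ---- Measurement CSV ------------------------------------------------------

#' Write / read a measurement table
#'
#' Measurement tables use a fixed CSV schema with header
#' `volume_id,slice,bin_label,voxel_count,measure_mm,fraction`; `slice` is
#' either a 1-based slice index or `"ALL"` for whole-volume rows, and
#' `measure_mm` is mm^3 (volume rows) or mm^2 (per-slice rows). Numbers are
#' written with full precision so a parse-back reproduces them.
#'
#' @param table a `measurement_table` data frame (from [measure_bins()] or
#'   [measure_slice_roi()]).
#' @param path CSV path.
#' @return `path` invisibly; `read_measurements` returns the table.
#' @export
write_measurements <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("cannot write an empty measurement table", call. = FALSE)
  need <- c("volume_id", "slice", "bin_label", "voxel_count", "measure_mm",
            "fraction")
  if (!all(need %in% names(table)))
    stop("measurement table lacks required columns: ",
         paste(setdiff(need, names(table)), collapse = ", "), call. = FALSE)
  out <- table[, need]
  for (col in c("voxel_count", "measure_mm", "fraction"))
    out[[col]] <- format(out[[col]], digits = 15, trim = TRUE,
                         scientific = FALSE)
  # fixed bare header; data fields quoted where needed (labels contain commas)
  writeLines(paste(need, collapse = ","), path)
  suppressWarnings(
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, append = TRUE, qmethod = "double"))
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(volume_id = "character",
                                        slice = "character",
                                        bin_label = "character"))
  tab$voxel_count <- as.numeric(tab$voxel_count)
  tab$measure_mm <- as.numeric(tab$measure_mm)
  tab$fraction <- as.numeric(tab$fraction)
  class(tab) <- c("measurement_table", "data.frame")
  tab
}
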