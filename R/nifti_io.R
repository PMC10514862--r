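# NIfTI import/export and on-disk format detection. NIfTI handling goes
# through RNifti; the internal grid's affine is stored/read as the sform
# (code 2, "aligned to another file"), never resampled.

#' Detect the on-disk image format of a path
#'
#' Classification is by content (magic numbers), not file extension: NIfTI-1
#' magic `n+1`/`ni1` (plain or gzipped), DICOM `DICM` marker at byte 128. For
#' a directory, the files inside are inspected.
#'
#' @param path File or directory path.
#' @return `"DICOM"`, `"NIFTI"` or `"UNKNOWN"`.
#' @export
detect_format <- function(path) {
  if (!file.exists(path)) return("UNKNOWN")
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    for (f in files) {
      fmt <- detect_file_format(f)
      if (fmt != "UNKNOWN") return(fmt)
    }
    return("UNKNOWN")
  }
  detect_file_format(path)
}

detect_file_format <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 4) return("UNKNOWN")
  head <- readBin(path, "raw", n = 4L)
  if (length(head) >= 2 && head[1] == as.raw(0x1f) && head[2] == as.raw(0x8b)) {
    # gzipped: look inside for the NIfTI-1 header
    con <- gzfile(path, open = "rb")
    on.exit(close(con))
    hdr <- tryCatch(readBin(con, "raw", n = 348L), error = function(e) raw())
    return(if (is_nifti1_header(hdr)) "NIFTI" else "UNKNOWN")
  }
  if (sz >= 348) {
    hdr <- readBin(path, "raw", n = 348L)
    if (is_nifti1_header(hdr)) return("NIFTI")
  }
  if (sz >= 132) {
    con <- file(path, open = "rb")
    on.exit(close(con))
    seek(con, 128L)
    magic <- readBin(con, "raw", n = 4L)
    if (identical(rawToChar(magic), "DICM")) return("DICOM")
  }
  "UNKNOWN"
}

is_nifti1_header <- function(hdr) {
  if (length(hdr) < 348) return(FALSE)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) return(FALSE)
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = "little")
  if (sizeof_hdr == 348L) return(TRUE)
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = "big")
  sizeof_hdr == 348L
}

#' Read a quantitative map from NIfTI or DICOM
#'
#' The format is auto-detected ([detect_format()]): `path` may be a
#' single-file NIfTI (optionally gzipped) or a directory containing exactly
#' one DICOM series. DICOM slices are sorted by the projection of their
#' position on the slice normal. Only 3D data are accepted.
#'
#' @param path NIfTI file or DICOM series directory.
#' @param name Map symbol to attach (e.g. `"T1"`).
#' @param units Map units, `"ms"` or `"arbitrary"`.
#' @return A [quantitative_map()].
#' @export
read_map <- function(path, name, units = c("ms", "arbitrary")) {
  units <- match.arg(units)
  fmt <- detect_format(path)
  if (fmt == "NIFTI") {
    vol <- read_nifti_volume(path)
  } else if (fmt == "DICOM") {
    vol <- read_dicom_series(path)
  } else {
    stop(sprintf("cannot determine image format of '%s'", path), call. = FALSE)
  }
  quantitative_map(name, vol$values, vol$grid, units = units)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  values <- array(as.numeric(values), dim(values))   # plain array, no header attributes
  nd <- length(dim(values))
  if (nd != 3L) {
    stop(sprintf("'%s' is %dD; only 3D volumes are supported (split 4D inputs first)",
                 path, nd), call. = FALSE)
  }
  affine <- unname(unclass(RNifti::xform(img)))
  attributes(affine) <- list(dim = dim(affine))
  # spacing from the affine column norms: the sform is authoritative here and
  # some writers leave pixdim at 1
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  grid <- ms_grid(dim(values), spacing = spacing, affine = affine)
  list(values = values, grid = grid)
}

#' Write a synthetic volume (or map) to NIfTI-1
#'
#' Writes a single-file NIfTI-1 image (gzipped when the path ends in `.gz`),
#' 32-bit float data, with the grid affine stored as the sform. No resampling
#' occurs: geometry passes through from the input grid.
#'
#' @param volume A `synth_volume` or `quant_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  if (inherits(volume, "quant_map")) {
    values <- volume$values; grid <- volume$grid
  } else if (inherits(volume, "synth_volume")) {
    values <- volume$values; grid <- volume$grid
  } else {
    stop("volume must be a synth_volume or quant_map", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("refusing to write non-finite voxel values", call. = FALSE)
  img <- RNifti::asNifti(values)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float32")
  invisible(path)
}
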