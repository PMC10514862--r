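# Minimal DICOM series I/O: MR Image Storage, Explicit VR Little Endian, one
# file per slice. This is a deliberately small, self-contained implementation
# scoped to synthetic-volume export and quantitative-map import: a
# code-generated template supplies the static tags, export updates the
# acquisition parameters (TR/TE/TI), window, series description and fresh
# UIDs, and pixel data are stored as 16-bit signed integers with a rescale
# slope/intercept back to physical signal units.

DICOM_TRANSFER_SYNTAX <- "1.2.840.10008.1.2.1"   # Explicit VR Little Endian
DICOM_MR_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.4"
DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Generate a fresh DICOM unique identifier
#'
#' UIDs use the `2.25.<decimal>` form with a random 38-digit suffix drawn
#' from the session RNG; every export generates fresh series/instance UIDs.
#'
#' @return A UID string.
#' @export
generate_uid <- function() {
  digits <- c(sample(1:9, 1L), sample(0:9, 37L, replace = TRUE))
  paste0("2.25.", paste(digits, collapse = ""))
}

#' Code-generated DICOM template
#'
#' A minimal MR Image Storage tag set carrying no patient data (the synthetic
#' subject id is filled at export time). It contains every mutable slot the
#' exporter updates: RepetitionTime, EchoTime, InversionTime, WindowCenter,
#' WindowWidth, SeriesDescription, and the UID slots.
#'
#' @return Named list of tag slots, each `list(group, element, vr, value)`.
#' @export
dicom_template <- function() {
  slot <- function(group, element, vr, value) {
    list(group = group, element = element, vr = vr, value = value)
  }
  list(
    ImageType          = slot(0x0008, 0x0008, "CS", "DERIVED\\SECONDARY"),
    SOPClassUID        = slot(0x0008, 0x0016, "UI", DICOM_MR_SOP_CLASS),
    SOPInstanceUID     = slot(0x0008, 0x0018, "UI", ""),
    StudyDate          = slot(0x0008, 0x0020, "DA", "20000101"),
    StudyTime          = slot(0x0008, 0x0030, "TM", "000000"),
    Modality           = slot(0x0008, 0x0060, "CS", "MR"),
    Manufacturer       = slot(0x0008, 0x0070, "LO", "mrisynth"),
    SeriesDescription  = slot(0x0008, 0x103E, "LO", "TEMPLATE"),
    PatientName        = slot(0x0010, 0x0010, "PN", "SYNTHETIC"),
    PatientID          = slot(0x0010, 0x0020, "LO", "SYNTHETIC"),
    PrivateCreator     = slot(0x0011, 0x0010, "LO", "mrisynth"),
    SynthParameters    = slot(0x0011, 0x1001, "LT", ""),
    SliceThickness     = slot(0x0018, 0x0050, "DS", ""),
    RepetitionTime     = slot(0x0018, 0x0080, "DS", ""),
    EchoTime           = slot(0x0018, 0x0081, "DS", ""),
    InversionTime      = slot(0x0018, 0x0082, "DS", ""),
    SpacingBetweenSlices = slot(0x0018, 0x0088, "DS", ""),
    StudyInstanceUID   = slot(0x0020, 0x000D, "UI", ""),
    SeriesInstanceUID  = slot(0x0020, 0x000E, "UI", ""),
    StudyID            = slot(0x0020, 0x0010, "SH", "1"),
    SeriesNumber       = slot(0x0020, 0x0011, "IS", "1"),
    InstanceNumber     = slot(0x0020, 0x0013, "IS", "1"),
    ImagePositionPatient    = slot(0x0020, 0x0032, "DS", "0\\0\\0"),
    ImageOrientationPatient = slot(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    FrameOfReferenceUID = slot(0x0020, 0x0052, "UI", ""),
    ImageComments      = slot(0x0020, 0x4000, "LT", ""),
    SamplesPerPixel    = slot(0x0028, 0x0002, "US", 1L),
    PhotometricInterpretation = slot(0x0028, 0x0004, "CS", "MONOCHROME2"),
    Rows               = slot(0x0028, 0x0010, "US", 0L),
    Columns            = slot(0x0028, 0x0011, "US", 0L),
    PixelSpacing       = slot(0x0028, 0x0030, "DS", "1\\1"),
    BitsAllocated      = slot(0x0028, 0x0100, "US", 16L),
    BitsStored         = slot(0x0028, 0x0101, "US", 16L),
    HighBit            = slot(0x0028, 0x0102, "US", 15L),
    PixelRepresentation = slot(0x0028, 0x0103, "US", 1L),
    WindowCenter       = slot(0x0028, 0x1050, "DS", ""),
    WindowWidth        = slot(0x0028, 0x1051, "DS", ""),
    RescaleIntercept   = slot(0x0028, 0x1052, "DS", "0"),
    RescaleSlope       = slot(0x0028, 0x1053, "DS", "1")
  )
}

DICOM_MUTABLE_SLOTS <- c("RepetitionTime", "EchoTime", "InversionTime",
                         "WindowCenter", "WindowWidth", "SeriesDescription",
                         "SOPInstanceUID", "SeriesInstanceUID", "StudyInstanceUID")

#' Export settings
#'
#' @param format `"nifti"` or `"dicom"`.
#' @param rescale_intercept DICOM rescale intercept (stored-to-physical map is
#'   `physical = stored * slope + intercept`); the slope is chosen per volume
#'   so the signal range fills the signed 16-bit integer range.
#' @param pattern Output naming pattern; `{subject}`, `{model}` and `{slice}`
#'   are substituted.
#' @return An object of class `export_settings`.
#' @export
export_settings <- function(format = c("nifti", "dicom"),
                            rescale_intercept = 0,
                            pattern = NULL) {
  format <- match.arg(format)
  if (is.null(pattern)) {
    pattern <- if (format == "dicom") "{subject}_{model}_{slice}.dcm" else "{subject}_{model}.nii.gz"
  }
  structure(list(format = format, rescale_intercept = rescale_intercept,
                 pattern = pattern),
            class = "export_settings")
}

fmt_ds <- function(x) {
  s <- formatC(signif(x, 8), format = "g", digits = 8)
  gsub(" ", "", s)
}

ds_join <- function(x) paste(vapply(x, fmt_ds, character(1)), collapse = "\\")

# --- byte-level encoding ----------------------------------------------------

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

encode_element <- function(group, element, vr, bytes) {
  len <- length(bytes)
  if (len %% 2L != 0L) stop("internal: odd element length", call. = FALSE)
  head <- c(raw_u16(group), raw_u16(element), charToRaw(vr))
  if (vr %in% DICOM_LONG_VRS) {
    c(head, as.raw(c(0, 0)), raw_u32(len), bytes)
  } else {
    if (len > 65534L) stop("element too long for short VR", call. = FALSE)
    c(head, raw_u16(len), bytes)
  }
}

encode_value <- function(vr, value) {
  if (vr %in% c("US",  "UL")) {
    if (vr == "US") return(raw_u16(value)) else return(raw_u32(value))
  }
  if (vr == "OW") return(value)  # already raw
  s <- as.character(value)
  b <- charToRaw(s)
  if (length(b) %% 2L != 0L) {
    b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  b
}

encode_slot <- function(slot) {
  encode_element(slot$group, slot$element, slot$vr, encode_value(slot$vr, slot$value))
}

encode_file_meta <- function(sop_instance_uid) {
  meta_slots <- list(
    list(group = 0x0002, element = 0x0001, vr = "OB", value = as.raw(c(0, 1))),
    list(group = 0x0002, element = 0x0002, vr = "UI", value = DICOM_MR_SOP_CLASS),
    list(group = 0x0002, element = 0x0003, vr = "UI", value = sop_instance_uid),
    list(group = 0x0002, element = 0x0010, vr = "UI", value = DICOM_TRANSFER_SYNTAX),
    list(group = 0x0002, element = 0x0012, vr = "UI", value = "2.25.777000111")
  )
  body <- unlist(lapply(meta_slots, function(s) {
    bytes <- if (s$vr == "OB") s$value else encode_value(s$vr, s$value)
    encode_element(s$group, s$element, s$vr, bytes)
  }))
  grouplen <- encode_element(0x0002, 0x0000, "UL", raw_u32(length(body)))
  c(raw(128L), charToRaw("DICM"), grouplen, body)
}

#' Write a synthetic volume as a DICOM series
#'
#' One Explicit VR Little Endian MR Image Storage file per slice. The
#' template's mutable slots are updated from the volume's provenance:
#' RepetitionTime/EchoTime/InversionTime from the scanner parameters (TR, TE,
#' TI — or TI1 when only a double-inversion pair is present; parameters with
#' no value leave the tag empty), SeriesDescription from the model name,
#' fresh Study/Series/SOP UIDs, a rescale slope/intercept mapping the stored
#' 16-bit integers back to physical signal, and a window covering the
#' 1st–99th percentile of the signal. The full parameter set is additionally
#' serialized as JSON into a private tag and ImageComments (TSAT and the
#' inversion pair have no standard tag of their own).
#'
#' @param volume A `synth_volume`.
#' @param template A [dicom_template()].
#' @param settings An [export_settings()] with `format = "dicom"`.
#' @param out_dir Output directory (created if needed).
#' @param subject Subject identifier used in filenames and PatientID.
#' @return Number of instances (files) written, invisibly.
#' @export
write_dicom <- function(volume, template = dicom_template(),
                        settings = export_settings("dicom"),
                        out_dir, subject = "SYN") {
  stopifnot(inherits(volume, "synth_volume"))
  if (any(!is.finite(volume$values))) {
    stop("refusing to write non-finite voxel values", call. = FALSE)
  }
  missing_slots <- setdiff(DICOM_MUTABLE_SLOTS, names(template))
  if (length(missing_slots)) {
    stop("template missing mutable slot(s): ", paste(missing_slots, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  v <- volume$values
  shape <- volume$grid$shape
  spacing <- volume$grid$spacing
  A <- volume$grid$affine

  # rescale: fill the signed 16-bit range
  maxabs <- max(abs(v))
  slope <- if (maxabs > 0) maxabs / 32767 else 1
  intercept <- settings$rescale_intercept
  stored <- round((v - intercept) / slope)

  # window over the 1st-99th percentile of the physical signal
  q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
  ww <- max(q[2] - q[1], slope)
  wc <- (q[1] + q[2]) / 2

  params <- volume$provenance$params
  pval <- function(sym) if (sym %in% names(params)) fmt_ds(params[[sym]]) else ""
  ti_tag <- if ("TI" %in% names(params)) pval("TI") else pval("TI1")
  params_json <- canonical_json(c(list(model = volume$provenance$model),
                                  lapply(as.list(unclass(params)), as.numeric)))
  params_json <- gsub("\n *", " ", params_json)

  # geometry: internal affine is RAS over 0-based voxel indices; DICOM wants
  # LPS direction cosines and positions
  ras2lps <- function(p) c(-p[1], -p[2], p[3])
  row_dir <- ras2lps(A[1:3, 1] / spacing[1])
  col_dir <- ras2lps(A[1:3, 2] / spacing[2])

  study_uid <- generate_uid()
  series_uid <- generate_uid()
  frame_uid <- generate_uid()

  tpl <- template
  tpl$PatientID$value <- subject
  tpl$SeriesDescription$value <- volume$provenance$model
  tpl$RepetitionTime$value <- pval("TR")
  tpl$EchoTime$value <- pval("TE")
  tpl$InversionTime$value <- ti_tag
  tpl$SliceThickness$value <- fmt_ds(spacing[3])
  tpl$SpacingBetweenSlices$value <- fmt_ds(spacing[3])
  tpl$StudyInstanceUID$value <- study_uid
  tpl$SeriesInstanceUID$value <- series_uid
  tpl$FrameOfReferenceUID$value <- frame_uid
  tpl$ImageOrientationPatient$value <- ds_join(c(row_dir, col_dir))
  tpl$ImageComments$value <- params_json
  tpl$SynthParameters$value <- params_json
  tpl$Rows$value <- shape[2]
  tpl$Columns$value <- shape[1]
  tpl$PixelSpacing$value <- ds_join(c(spacing[2], spacing[1]))
  tpl$WindowCenter$value <- fmt_ds(wc)
  tpl$WindowWidth$value <- fmt_ds(ww)
  tpl$RescaleIntercept$value <- fmt_ds(intercept)
  tpl$RescaleSlope$value <- fmt_ds(slope)

  model <- volume$provenance$model
  n_written <- 0L
  for (k in seq_len(shape[3])) {
    sop_uid <- generate_uid()
    slice <- tpl
    slice$SOPInstanceUID$value <- sop_uid
    slice$InstanceNumber$value <- as.character(k)
    ipp <- ras2lps((A %*% c(0, 0, k - 1, 1))[1:3])
    slice$ImagePositionPatient$value <- ds_join(ipp)

    # pixel row-major order (rows = voxel axis 2) equals R's column-major
    # order of the slice matrix
    pix <- writeBin(as.integer(stored[, , k]), raw(), size = 2L, endian = "little")
    body <- unlist(lapply(slice, encode_slot))
    body <- c(body, encode_element(0x7FE0, 0x0010, "OW", pix))

    fname <- settings$pattern
    fname <- gsub("{subject}", subject, fname, fixed = TRUE)
    fname <- gsub("{model}", model, fname, fixed = TRUE)
    fname <- gsub("{slice}", sprintf("%03d", k), fname, fixed = TRUE)
    path <- file.path(out_dir, fname)
    con <- file(path, open = "wb")
    writeBin(c(encode_file_meta(sop_uid), body), con)
    close(con)
    n_written <- n_written + 1L
  }
  invisible(n_written)
}

# --- parsing ----------------------------------------------------------------

parse_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132 || !identical(rawToChar(bytes[129:132]), "DICM")) {
    stop(sprintf("'%s' is not a DICOM file", path), call. = FALSE)
  }
  pos <- 133L
  n <- length(bytes)
  u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2L,
                              signed = FALSE, endian = "little")
  u32at <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4L,
                                endian = "little")
  elements <- list()
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop(sprintf("'%s': implicit VR or corrupt element at offset %d", path, pos - 1L),
           call. = FALSE)
    }
    if (vr %in% DICOM_LONG_VRS) {
      len <- u32at(pos + 8L)
      data_start <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      data_start <- pos + 8L
    }
    if (len < 0L || is.na(len)) {
      stop(sprintf("'%s': undefined-length element not supported", path), call. = FALSE)
    }
    value <- if (len > 0L) bytes[data_start:(data_start + len - 1L)] else raw()
    key <- sprintf("%04X,%04X", group, element)
    elements[[key]] <- list(vr = vr, bytes = value)
    pos <- data_start + len
  }
  elements
}

dcm_string <- function(el) {
  if (is.null(el)) return(NA_character_)
  b <- el$bytes
  pad <- c(as.raw(0L), charToRaw(" "))
  while (length(b) && b[length(b)] %in% pad) b <- b[-length(b)]
  rawToChar(b)
}
dcm_numbers <- function(el) {
  s <- dcm_string(el)
  if (is.na(s) || !nzchar(s)) return(numeric())
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}
dcm_u16 <- function(el) {
  readBin(el$bytes, "integer", size = 2L, signed = FALSE, endian = "little")
}

#' Read a DICOM series from a directory
#'
#' Reads all DICOM files in `dir` (one series expected), sorts slices by the
#' projection of ImagePositionPatient on the slice normal, applies the
#' rescale slope/intercept, and reconstructs the voxel grid geometry (RAS
#' affine) from the orientation/position tags.
#'
#' @param dir Directory containing exactly one DICOM series.
#' @return List with `values` (3D array, physical units), `grid`
#'   ([ms_grid()]) and `meta` (series description, TR/TE/TI strings).
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  files <- files[vapply(files, function(f) detect_file_format(f) == "DICOM", logical(1))]
  if (length(files) == 0L) stop(sprintf("no DICOM files in '%s'", dir), call. = FALSE)

  slices <- lapply(files, parse_dicom_file)
  series_uids <- unique(vapply(slices, function(el) dcm_string(el[["0020,000E"]]), character(1)))
  if (length(series_uids) != 1L) {
    stop(sprintf("directory '%s' contains %d DICOM series; expected exactly one",
                 dir, length(series_uids)), call. = FALSE)
  }

  first <- slices[[1L]]
  rows <- dcm_u16(first[["0028,0010"]])
  cols <- dcm_u16(first[["0028,0011"]])
  iop <- dcm_numbers(first[["0020,0037"]])
  pixsp <- dcm_numbers(first[["0028,0030"]])
  stopifnot(length(iop) == 6L, length(pixsp) == 2L)
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])

  ipps <- lapply(slices, function(el) dcm_numbers(el[["0020,0032"]]))
  proj <- vapply(ipps, function(p) sum(p * normal), numeric(1))
  ord <- order(proj)
  slices <- slices[ord]
  ipps <- ipps[ord]

  nz <- length(slices)
  values <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    el <- slices[[k]]
    stopifnot(dcm_u16(el[["0028,0010"]]) == rows, dcm_u16(el[["0028,0011"]]) == cols)
    slope <- dcm_numbers(el[["0028,1053"]])
    intercept <- dcm_numbers(el[["0028,1052"]])
    slope <- if (length(slope)) slope else 1
    intercept <- if (length(intercept)) intercept else 0
    signed <- TRUE
    pr <- el[["0028,0103"]]
    if (!is.null(pr)) signed <- dcm_u16(pr) == 1L
    stored <- readBin(el[["7FE0,0010"]]$bytes, "integer", n = rows * cols,
                      size = 2L, signed = signed, endian = "little")
    values[, , k] <- array(stored, dim = c(cols, rows)) * slope + intercept
  }

  lps2ras <- function(p) c(-p[1], -p[2], p[3])
  dx <- pixsp[2]; dy <- pixsp[1]
  if (nz > 1L) {
    step <- (ipps[[nz]] - ipps[[1L]]) / (nz - 1L)
  } else {
    st <- dcm_numbers(first[["0018,0050"]])
    step <- normal * (if (length(st)) st else 1)
  }
  dz <- sqrt(sum(step^2))
  affine <- diag(4)
  affine[1:3, 1] <- lps2ras(row_dir) * dx
  affine[1:3, 2] <- lps2ras(col_dir) * dy
  affine[1:3, 3] <- lps2ras(step)
  affine[1:3, 4] <- lps2ras(ipps[[1L]])
  grid <- ms_grid(c(cols, rows, nz), spacing = c(dx, dy, dz), affine = affine)

  meta <- list(
    series_description = dcm_string(first[["0008,103E"]]),
    repetition_time = dcm_string(first[["0018,0080"]]),
    echo_time = dcm_string(first[["0018,0081"]]),
    inversion_time = dcm_string(first[["0018,0082"]]),
    comments = dcm_string(first[["0020,4000"]])
  )
  list(values = values, grid = grid, meta = meta)
}
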