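# Minimal single-frame DICOM support: explicit and implicit VR little endian,
# uncompressed pixel data, the tag set needed for volume reconstruction
# (InstanceNumber, PixelSpacing, SliceThickness, Rows/Columns, pixel layout,
# RescaleSlope/Intercept).  Multi-frame/enhanced DICOM and sequences with
# undefined length are out of scope.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

.u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.u32 <- function(raw4) {
  as.numeric(raw4[1]) + 256 * as.numeric(raw4[2]) +
    65536 * as.numeric(raw4[3]) + 16777216 * as.numeric(raw4[4])
}
.raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
.raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                 endian = "little")

# VRs that use the 4-byte length form under explicit VR
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dicom_pad <- function(value, vr) {
  if (is.raw(value)) {
    if (length(value) %% 2 == 1) value <- c(value, as.raw(0))
    return(value)
  }
  s <- as.character(value)
  b <- charToRaw(s)
  if (length(b) %% 2 == 1)
    b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
  b
}

.dicom_encode_element <- function(group, element, vr, value) {
  body <- if (vr == "US") {
    .raw_u16(value)
  } else if (vr == "UL") {
    .raw_u32(value)
  } else if (vr %in% c("OB", "OW")) {
    .dicom_pad(value, vr)
  } else {
    .dicom_pad(value, vr)
  }
  hdr <- c(.raw_u16(group), .raw_u16(element), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), .raw_u32(length(body)), body)
  } else {
    c(hdr, .raw_u16(length(body)), body)
  }
}

# Write one DICOM file from an explicit element list; each element is
# list(group, element, vr, value).  Used by writeDicomSeries and, with
# deliberately incomplete tag lists, by the test suite.
.dicomWriteFile <- function(path, elements) {
  meta <- c(
    .dicom_encode_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dicom_encode_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    .dicom_encode_element(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.9999.2"),
    .dicom_encode_element(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .dicom_encode_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.1"))
  grouplen <- .dicom_encode_element(0x0002, 0x0000, "UL", length(meta))
  body <- unlist(lapply(elements, function(e)
    .dicom_encode_element(e$group, e$element, e$vr, e$value)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta, body), con)
  invisible(path)
}

# implicit-VR dictionary for the tags the reader interprets
.DICOM_DICT <- list(
  "0008,0016" = "UI", "0008,0018" = "UI",
  "0018,0050" = "DS",
  "0020,000d" = "UI", "0020,000e" = "UI", "0020,0013" = "IS",
  "0028,0002" = "US", "0028,0004" = "CS",
  "0028,0010" = "US", "0028,0011" = "US", "0028,0030" = "DS",
  "0028,0100" = "US", "0028,0101" = "US", "0028,0102" = "US",
  "0028,0103" = "US", "0028,1052" = "DS", "0028,1053" = "DS",
  "7fe0,0010" = "OW")

.tag_key <- function(group, element) sprintf("%04x,%04x", group, element)

# Parse one DICOM file into a named list of decoded elements.
.dicomParseFile <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  ts <- .TS_EXPLICIT_LE
  out <- list()
  explicit <- TRUE
  in_meta <- TRUE
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- .u16(raw[pos:(pos + 1L)])
    element <- .u16(raw[(pos + 2L):(pos + 3L)])
    if (in_meta && group != 0x0002) {
      in_meta <- FALSE
      explicit <- !identical(ts, .TS_IMPLICIT_LE)
    }
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .LONG_VRS) {
        len <- .u32(raw[(pos + 8L):(pos + 11L)])
        vstart <- pos + 12L
      } else {
        len <- .u16(raw[(pos + 6L):(pos + 7L)])
        vstart <- pos + 8L
      }
    } else {
      key <- .tag_key(group, element)
      vr <- if (!is.null(.DICOM_DICT[[key]])) .DICOM_DICT[[key]] else "UN"
      len <- .u32(raw[(pos + 4L):(pos + 7L)])
      vstart <- pos + 8L
    }
    if (len == 4294967295)
      stop("undefined-length element not supported: ",
           .tag_key(group, element), " in ", path)
    if (vstart + len - 1L > n)
      stop("truncated DICOM element ", .tag_key(group, element), " in ", path)
    val_raw <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    key <- .tag_key(group, element)
    out[[key]] <- switch(vr,
      US = .u16(val_raw[1:2]),
      UL = .u32(val_raw[1:4]),
      DS = as.numeric(strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1]]),
      IS = as.integer(strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1]]),
      UI = , CS = trimws(rawToChar(val_raw)),
      OW = , OB = val_raw,
      val_raw)
    if (key == "0002,0010") ts <- trimws(out[[key]])
    pos <- vstart + as.integer(len)
  }
  out
}

.dicom_require <- function(parsed, key, name, path) {
  if (is.null(parsed[[key]]))
    stop("DICOM metadata error: required tag ", name, " (", key,
         ") missing in ", path)
  parsed[[key]]
}

.dicom_decode_pixels <- function(parsed, path) {
  rows <- .dicom_require(parsed, "0028,0010", "Rows", path)
  cols <- .dicom_require(parsed, "0028,0011", "Columns", path)
  bits <- parsed[["0028,0100"]]
  if (is.null(bits)) bits <- 16L
  pixrep <- parsed[["0028,0103"]]
  if (is.null(pixrep)) pixrep <- 0L
  pd <- .dicom_require(parsed, "7fe0,0010", "PixelData", path)
  npx <- rows * cols
  vals <- if (bits == 8) {
    as.numeric(readBin(pd, "integer", n = npx, size = 1, signed = FALSE))
  } else if (bits == 16) {
    as.numeric(readBin(pd, "integer", n = npx, size = 2,
                       signed = pixrep == 1L, endian = "little"))
  } else stop("unsupported BitsAllocated ", bits, " in ", path)
  if (length(vals) < npx)
    stop("PixelData shorter than Rows*Columns in ", path)
  # DICOM pixel data is row-major (column index fastest within a row)
  vals <- as.vector(t(matrix(vals, nrow = cols, ncol = rows)))
  slope <- parsed[["0028,1053"]]
  intercept <- parsed[["0028,1052"]]
  if (!is.null(slope) || !is.null(intercept)) {
    if (is.null(slope)) slope <- 1
    if (is.null(intercept)) intercept <- 0
    vals <- vals * slope + intercept
  }
  matrix(vals, nrow = rows, ncol = cols)
}

#' Read a DICOM series into a volume
#'
#' Reads all single-frame DICOM files in a directory, stacks them in
#' ascending `InstanceNumber` along z, and assembles the voxel spacing from
#' `PixelSpacing` and `SliceThickness`. The standard DICOM rescale
#' (`RescaleSlope`/`RescaleIntercept`) is applied when present. Intensities
#' are promoted to double.
#'
#' @param directory path containing at least two DICOM slice files of one
#'   series with identical in-plane dimensions.
#' @param pattern filename filter passed to [list.files()] (default all
#'   files).
#' @return `list(volume = VolumeGrid, meta = DicomSeriesMeta)`; the volume is
#'   generally anisotropic (pass to [resampleIsotropic]).
#' @seealso [writeDicomSeries], [resampleIsotropic]
#' @export
readDicomSeries <- function(directory, pattern = NULL) {
  if (!dir.exists(directory)) stop("not a directory: ", directory)
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2)
    stop("cannot form a volume: need at least 2 DICOM slices, found ",
         length(files))
  slices <- vector("list", length(files))
  inst <- integer(length(files))
  ps <- st <- NULL
  dims <- NULL
  for (i in seq_along(files)) {
    p <- .dicomParseFile(files[i])
    inst[i] <- .dicom_require(p, "0020,0013", "InstanceNumber", files[i])[1]
    ps_i <- .dicom_require(p, "0028,0030", "PixelSpacing", files[i])
    st_i <- .dicom_require(p, "0018,0050", "SliceThickness", files[i])[1]
    m <- .dicom_decode_pixels(p, files[i])
    if (is.null(dims)) {
      dims <- dim(m); ps <- ps_i; st <- st_i
    } else if (!all(dim(m) == dims)) {
      stop("shape error: slice ", basename(files[i]), " is ",
           paste(dim(m), collapse = "x"), ", expected ",
           paste(dims, collapse = "x"))
    }
    slices[[i]] <- m
  }
  if (anyDuplicated(inst))
    stop("duplicate InstanceNumber values in series: ",
         paste(unique(inst[duplicated(inst)]), collapse = ", "))
  ord <- order(inst)
  vol <- array(0, c(dims, length(files)))
  for (z in seq_along(ord)) vol[, , z] <- slices[[ord[z]]]
  meta <- new("DicomSeriesMeta", instanceNumbers = as.integer(inst[ord]),
              pixelSpacing = as.numeric(ps[1:2]),
              sliceThickness = as.numeric(st))
  list(volume = VolumeGrid(vol, spacing = c(ps[1], ps[2], st)), meta = meta)
}

#' Write a volume as a minimal DICOM series
#'
#' Writes one single-frame DICOM file per z slice (explicit VR little
#' endian, 16-bit unsigned pixels with `RescaleSlope`/`RescaleIntercept`
#' expressing the original floating-point intensities). Slice `z` gets
#' `InstanceNumber z`. Intended for exercising [readDicomSeries] end-to-end
#' with phantom data.
#'
#' @param volume a [VolumeGrid-class]; `spacing` supplies PixelSpacing (x, y)
#'   and SliceThickness (z).
#' @param directory output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the written file paths.
#' @export
writeDicomSeries <- function(volume, directory, prefix = "slice") {
  stopifnot(is(volume, "VolumeGrid"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  a <- volume@intensities
  d <- dim(a)
  sp <- volume@spacing
  rng <- range(a)
  slope <- if (rng[2] > rng[1]) (rng[2] - rng[1]) / 65535 else 1
  intercept <- rng[1]
  stored <- round((a - intercept) / slope)
  paths <- character(d[3])
  series_uid <- "1.2.826.0.1.3680043.9999.3.1"
  study_uid <- "1.2.826.0.1.3680043.9999.3"
  for (z in seq_len(d[3])) {
    # DICOM pixel data is row-major: emit with the column index fastest
    px <- writeBin(as.integer(t(stored[, , z])), raw(), size = 2,
                   endian = "little")
    elements <- list(
      list(group = 0x0008, element = 0x0016, vr = "UI",
           value = "1.2.840.10008.5.1.4.1.1.7"),
      list(group = 0x0008, element = 0x0018, vr = "UI",
           value = paste0(series_uid, ".", z)),
      list(group = 0x0018, element = 0x0050, vr = "DS",
           value = format(sp[3], digits = 10)),
      list(group = 0x0020, element = 0x000D, vr = "UI", value = study_uid),
      list(group = 0x0020, element = 0x000E, vr = "UI", value = series_uid),
      list(group = 0x0020, element = 0x0013, vr = "IS",
           value = as.character(z)),
      list(group = 0x0028, element = 0x0002, vr = "US", value = 1L),
      list(group = 0x0028, element = 0x0004, vr = "CS", value = "MONOCHROME2"),
      list(group = 0x0028, element = 0x0010, vr = "US", value = d[1]),
      list(group = 0x0028, element = 0x0011, vr = "US", value = d[2]),
      list(group = 0x0028, element = 0x0030, vr = "DS",
           value = paste(format(sp[1], digits = 10),
                         format(sp[2], digits = 10), sep = "\\")),
      list(group = 0x0028, element = 0x0100, vr = "US", value = 16L),
      list(group = 0x0028, element = 0x0101, vr = "US", value = 16L),
      list(group = 0x0028, element = 0x0102, vr = "US", value = 15L),
      list(group = 0x0028, element = 0x0103, vr = "US", value = 0L),
      list(group = 0x0028, element = 0x1052, vr = "DS",
           value = format(intercept, digits = 10)),
      list(group = 0x0028, element = 0x1053, vr = "DS",
           value = format(slope, digits = 10)),
      list(group = 0x7FE0, element = 0x0010, vr = "OW", value = px))
    paths[z] <- file.path(directory, sprintf("%s_%04d.dcm", prefix, z))
    .dicomWriteFile(paths[z], elements)
  }
  invisible(paths)
}
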