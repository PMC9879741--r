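## Image input/output. All format dialects live here; the rest of the package
## only sees Volume3D / Localizer2D.
##
## DICOM support is a deliberately small, self-contained dialect: single-frame
## CT slices and scout views, explicit-VR little-endian transfer syntax,
## uncompressed 16-bit pixel data with rescale slope/intercept, and the
## geometry tags the pipeline needs (ImagePositionPatient,
## ImageOrientationPatient, PixelSpacing, TableHeight, instance/series UIDs).
## The writer expresses geometry in an isocenter-centred DICOM patient frame
## (LPS; the gantry isocenter at x = y = 0), so a reader can recover the
## scanner-frame vertical axis without vendor-specific conventions.
##
## Scanner frame <-> DICOM patient frame:
##   DICOM x = lateral (patient left +), DICOM y = -(vertical - isocenterY),
##   DICOM z = longitudinal. TableHeight (0018,1130) is stored as the vertical
##   distance from the table top to the isocenter (positive = table below).

DCM_UID_ROOT <- "1.2.826.0.1.3680043.9717"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

uint16le <- function(v) {
  v <- as.integer(v)
  as.raw(rbind(v %% 256L, v %/% 256L))
}
uint32le <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

dcmElement <- function(group, element, vr, value) {
  if (is.raw(value)) {
    payload <- value
  } else {
    s <- paste(value, collapse = "\\")
    payload <- charToRaw(s)
    if (length(payload) %% 2L == 1L)
      payload <- c(payload, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  hdr <- c(uint16le(group), uint16le(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), uint32le(length(payload)), payload)
  } else {
    c(hdr, uint16le(length(payload)), payload)
  }
}

dcmNumber <- function(x) sprintf("%.6f", x)

## Serialize one image (slice or scout) to DICOM part-10 bytes.
dcmWriteFile <- function(path, elements) {
  meta <- c(
    dcmElement(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcmElement(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcmElement(0x0002, 0x0003, "UI", paste0(DCM_UID_ROOT, ".0")),
    dcmElement(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  groupLen <- dcmElement(0x0002, 0x0000, "UL", uint32le(length(meta)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(groupLen, meta, elements), con)
  invisible(path)
}

pixelPayload <- function(values) {
  ints <- as.integer(round(values * 1e4))
  if (any(ints < 0L | ints > 32767L))
    stop("pixel intensities outside the storable [0, 3.2767] range")
  uint16le(ints)
}

#' Write a Volume3D as a DICOM axial series
#'
#' One explicit-VR little-endian file per axial slice, 16-bit pixels with
#' RescaleSlope 1e-4 (exactly lossless for rendered phantoms, whose
#' intensities live on a 1e-4 grid). Geometry is written in an
#' isocenter-centred patient frame; see the module header.
#'
#' @param volume a \code{\link{Volume3D-class}} (axial orientation).
#' @param dir output directory (created if missing).
#' @param seriesId integer stamped into the series UID and filenames.
#' @param sourceId scanner/centre label, stored as StationName.
#' @return Invisibly, the written file paths.
#' @export
writeDicomSeries <- function(volume, dir, seriesId = 1L, sourceId = "sim") {
  if (volume@orientationTag != "axial") stop("series writer expects axial data")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- volume@grid
  y <- axisCoords(g, 1); x <- axisCoords(g, 2); z <- axisCoords(g, 3)
  iso <- g@isocenterY
  seriesUid <- paste0(DCM_UID_ROOT, ".", seriesId)
  th <- if (is.finite(volume@tableHeight)) iso - volume@tableHeight else NA
  paths <- character(g@shape[3])
  for (k in seq_len(g@shape[3])) {
    ## DICOM rows run anterior -> posterior: flip the vertical axis
    slice <- volume@voxels[rev(seq_len(g@shape[1])), , k]
    ipp <- c(x[1], -(max(y) - iso), z[k])
    els <- c(
      dcmElement(0x0008, 0x0008, "CS", "ORIGINAL\\PRIMARY\\AXIAL"),
      dcmElement(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcmElement(0x0008, 0x0018, "UI", paste0(seriesUid, ".", k)),
      dcmElement(0x0008, 0x0060, "CS", "CT"),
      dcmElement(0x0008, 0x1010, "SH", sourceId),
      if (is.finite(th)) dcmElement(0x0018, 0x1130, "DS", dcmNumber(th)),
      dcmElement(0x0020, 0x000D, "UI", paste0(seriesUid, ".9")),
      dcmElement(0x0020, 0x000E, "UI", seriesUid),
      dcmElement(0x0020, 0x0013, "IS", as.character(k)),
      dcmElement(0x0020, 0x0032, "DS", dcmNumber(ipp)),
      dcmElement(0x0020, 0x0037, "DS",
                 dcmNumber(c(1, 0, 0, 0, 1, 0))),
      dcmElement(0x0020, 0x1041, "DS", dcmNumber(z[k])),
      dcmElement(0x0028, 0x0010, "US", uint16le(g@shape[1])),
      dcmElement(0x0028, 0x0011, "US", uint16le(g@shape[2])),
      dcmElement(0x0028, 0x0030, "DS",
                 dcmNumber(c(g@spacing[1], g@spacing[2]))),
      dcmElement(0x0028, 0x0100, "US", uint16le(16L)),
      dcmElement(0x0028, 0x0101, "US", uint16le(16L)),
      dcmElement(0x0028, 0x0102, "US", uint16le(15L)),
      dcmElement(0x0028, 0x0103, "US", uint16le(0L)),
      dcmElement(0x0028, 0x1052, "DS", "0"),
      dcmElement(0x0028, 0x1053, "DS", "0.0001"),
      ## DICOM pixel order is row-major: transpose the (row, col) slice
      dcmElement(0x7FE0, 0x0010, "OW", pixelPayload(t(slice))))
    paths[k] <- file.path(dir, sprintf("slice%04d.dcm", k))
    dcmWriteFile(paths[k], els)
  }
  invisible(paths)
}

#' Write a Localizer2D as a DICOM scout view
#'
#' Rows run superior -> inferior as on a console display; the reader flips
#' back into the package's superior-positive Z axis.
#'
#' @param localizer a \code{\link{Localizer2D-class}}.
#' @param path output file.
#' @param seriesId integer for the UID.
#' @return Invisibly, \code{path}.
#' @export
writeDicomScout <- function(localizer, path, seriesId = 1L) {
  p <- localizer@pixels
  nz <- nrow(p); nx <- ncol(p)
  zTop <- localizer@position[1] + (nz - 1) * localizer@pixelSpacing[1]
  seriesUid <- paste0(DCM_UID_ROOT, ".", seriesId, ".100")
  els <- c(
    dcmElement(0x0008, 0x0008, "CS", "ORIGINAL\\PRIMARY\\LOCALIZER"),
    dcmElement(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcmElement(0x0008, 0x0018, "UI", paste0(seriesUid, ".1")),
    dcmElement(0x0008, 0x0060, "CS", "CT"),
    dcmElement(0x0008, 0x1010, "SH", localizer@sourceId),
    dcmElement(0x0020, 0x000D, "UI", paste0(seriesUid, ".9")),
    dcmElement(0x0020, 0x000E, "UI", seriesUid),
    dcmElement(0x0020, 0x0013, "IS", "1"),
    dcmElement(0x0020, 0x0032, "DS",
               dcmNumber(c(localizer@position[2], 0, zTop))),
    dcmElement(0x0020, 0x0037, "DS", dcmNumber(c(1, 0, 0, 0, 0, -1))),
    dcmElement(0x0028, 0x0010, "US", uint16le(nz)),
    dcmElement(0x0028, 0x0011, "US", uint16le(nx)),
    dcmElement(0x0028, 0x0030, "DS",
               dcmNumber(localizer@pixelSpacing)),
    dcmElement(0x0028, 0x0100, "US", uint16le(16L)),
    dcmElement(0x0028, 0x0101, "US", uint16le(16L)),
    dcmElement(0x0028, 0x0102, "US", uint16le(15L)),
    dcmElement(0x0028, 0x0103, "US", uint16le(0L)),
    dcmElement(0x0028, 0x1052, "DS", "0"),
    dcmElement(0x0028, 0x1053, "DS", "0.0001"),
    dcmElement(0x7FE0, 0x0010, "OW",
               pixelPayload(t(p[rev(seq_len(nz)), , drop = FALSE]))))
  dcmWriteFile(path, els)
  invisible(path)
}

## ---- reading --------------------------------------------------------------

rawU16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
rawU32 <- function(r, i) {
  as.numeric(r[i]) + 256 * as.numeric(r[i + 1L]) +
    65536 * as.numeric(r[i + 2L]) + 16777216 * as.numeric(r[i + 3L])
}

## Parse an explicit-VR little-endian part-10 file into a tag -> value list.
dcmParse <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  i <- 133L
  out <- list()
  n <- length(r)
  while (i + 7L <= n) {
    group <- rawU16(r, i); element <- rawU16(r, i + 2L)
    vr <- rawToChar(r[(i + 4L):(i + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupt element in ", path)
    if (vr %in% LONG_VRS) {
      len <- rawU32(r, i + 8L); start <- i + 12L
    } else {
      len <- rawU16(r, i + 6L); start <- i + 8L
    }
    key <- sprintf("%04X,%04X", group, element)
    val <- if (len > 0) r[start:(start + len - 1L)] else raw(0)
    out[[key]] <- list(vr = vr, bytes = val)
    i <- start + len
  }
  out
}

dcmString <- function(tags, key) {
  e <- tags[[key]]
  if (is.null(e)) return(NULL)
  b <- e$bytes
  while (length(b) && b[length(b)] == as.raw(0)) b <- b[-length(b)]
  sub("[ \t]+$", "", rawToChar(b))
}
dcmNumeric <- function(tags, key) {
  s <- dcmString(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcmU16Values <- function(tags, key) {
  e <- tags[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$bytes, "integer", n = length(e$bytes) / 2L, size = 2L,
          signed = FALSE, endian = "little")
}

dcmRequire <- function(value, attrName, path) {
  if (is.null(value))
    stop("missing DICOM attribute ", attrName, " in ", basename(path))
  value
}

dcmPixelMatrix <- function(tags, path) {
  rows <- dcmRequire(dcmU16Values(tags, "0028,0010"), "Rows", path)
  cols <- dcmRequire(dcmU16Values(tags, "0028,0011"), "Columns", path)
  slope <- dcmNumeric(tags, "0028,1053"); if (is.null(slope)) slope <- 1
  icpt <- dcmNumeric(tags, "0028,1052"); if (is.null(icpt)) icpt <- 0
  px <- dcmRequire(dcmU16Values(tags, "7FE0,0010"), "PixelData", path)
  ## stored row-major; R fills column-major, so build transposed and flip
  m <- t(matrix(px * slope + icpt, nrow = cols, ncol = rows))
  m
}

#' Read a DICOM axial series into a Volume3D
#'
#' Slices are sorted by longitudinal position regardless of on-disk order;
#' a mixed series, a non-uniform slice gap (beyond \code{tolerance} mm) or
#' missing spacing metadata is an error naming the offending attribute.
#'
#' @param path directory containing one single-frame axial series.
#' @param tolerance mm tolerance on slice-gap uniformity.
#' @return A \code{\link{Volume3D-class}} with \code{isocenterY = 0} (the
#'   writer's isocenter-centred frame).
#' @export
readAxialSeries <- function(path, tolerance = 1e-3) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no DICOM files in ", path)
  parsed <- lapply(files, dcmParse)
  series <- vapply(parsed, function(t) dcmString(t, "0020,000E"), "")
  if (length(unique(series)) != 1L)
    stop("mixed SeriesInstanceUID values in ", path)
  zpos <- vapply(seq_along(parsed), function(i)
    dcmRequire(dcmNumeric(parsed[[i]], "0020,0032"),
               "ImagePositionPatient", files[i])[3], 0)
  ord <- order(zpos)
  parsed <- parsed[ord]; files <- files[ord]; zpos <- zpos[ord]
  if (length(zpos) > 1) {
    gaps <- diff(zpos)
    if (any(gaps <= 0) || diff(range(gaps)) > tolerance)
      stop("non-uniform slice spacing (SliceLocation/ImagePositionPatient) in ",
           path)
  }
  spacing2d <- dcmRequire(dcmNumeric(parsed[[1]], "0028,0030"),
                          "PixelSpacing", files[1])
  ipp <- dcmNumeric(parsed[[1]], "0020,0032")
  slices <- lapply(seq_along(parsed), function(i)
    dcmPixelMatrix(parsed[[i]], files[i]))
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]])
  vox <- array(0, dim = c(ny, nx, length(slices)))
  for (k in seq_along(slices))
    vox[, , k] <- slices[[k]][rev(seq_len(ny)), ]   # back to anterior-positive
  dz <- if (length(zpos) > 1) mean(diff(zpos)) else spacing2d[1]
  yTop <- -ipp[2]                                   # DICOM y -> scanner y
  origin <- c(yTop - (ny - 1) * spacing2d[1], ipp[1], zpos[1])
  grid <- Grid3D(c(ny, nx, length(slices)),
                 c(spacing2d[1], spacing2d[2], dz),
                 origin = origin, isocenterY = 0)
  thRaw <- dcmNumeric(parsed[[1]], "0018,1130")
  th <- if (is.null(thRaw)) NA_real_ else -thRaw
  Volume3D(vox, grid, tableHeight = th)
}

#' Read a DICOM scout view into a Localizer2D
#'
#' @param path one DICOM file written by \code{\link{writeDicomScout}} or an
#'   equivalent single-frame scout.
#' @return A \code{\link{Localizer2D-class}}.
#' @export
readLocalizer <- function(path) {
  tags <- dcmParse(path)
  sp <- dcmRequire(dcmNumeric(tags, "0028,0030"), "PixelSpacing", path)
  ipp <- dcmRequire(dcmNumeric(tags, "0020,0032"), "ImagePositionPatient", path)
  m <- dcmPixelMatrix(tags, path)
  nz <- nrow(m)
  pix <- m[rev(seq_len(nz)), , drop = FALSE]        # superior-positive Z
  zLow <- ipp[3] - (nz - 1) * sp[1]
  station <- dcmString(tags, "0008,1010")
  Localizer2D(pix, pixelSpacing = sp, position = c(zLow, ipp[1]),
              sourceId = if (is.null(station)) "unknown" else station)
}

## ---- NIfTI ----------------------------------------------------------------

#' Write / read a Volume3D as NIfTI (+ JSON geometry sidecar)
#'
#' NIfTI stores spacing natively; the scanner-frame origin, isocenter and
#' table height go into a small JSON sidecar next to the image.
#'
#' @param volume a \code{\link{Volume3D-class}}.
#' @param path output path ending in .nii or .nii.gz.
#' @return \code{writeVolumeNifti}: invisibly, \code{path};
#'   \code{readVolumeNifti}: a \code{Volume3D}.
#' @export
writeVolumeNifti <- function(volume, path) {
  img <- RNifti::asNifti(volume@voxels,
                         reference = list(pixdim = c(1, volume@grid@spacing, 1, 1, 1, 1)))
  RNifti::writeNifti(img, path, datatype = "double")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(origin = volume@grid@origin,
                            spacing = volume@grid@spacing,
                            isocenterY = volume@grid@isocenterY,
                            tableHeight = volume@tableHeight,
                            orientation = volume@orientationTag),
                       sidecar, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname writeVolumeNifti
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  arr <- array(as.numeric(img), dim = dim(img))
  grid <- Grid3D(dim(arr), as.numeric(meta$spacing),
                 origin = as.numeric(meta$origin),
                 isocenterY = as.numeric(meta$isocenterY))
  th <- if (is.null(meta$tableHeight) || !is.numeric(meta$tableHeight))
    NA_real_ else as.numeric(meta$tableHeight)
  Volume3D(arr, grid, tableHeight = th,
           orientationTag = as.character(meta$orientation))
}
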