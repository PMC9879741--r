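#' @import methods
#' @importFrom stats rnorm runif median quantile sd cor pnorm pt qnorm ks.test
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib ctcenterline, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Package-wide axis convention (all arrays, all readers convert into it):
##   axis 1: vertical / anterior-posterior, positive toward anterior (up)
##   axis 2: lateral, positive toward patient left
##   axis 3: longitudinal (Z), positive toward superior
## The gantry isocenter sits at a fixed vertical coordinate `isocenterY`
## (0 by default), so signed vertical positions read directly as mis-centering.

#' Axial voxel lattice in the scanner frame
#'
#' A \code{Grid3D} describes where a voxel array lives in physical scanner
#' coordinates: integer shape, strictly positive spacing (mm), the mm position
#' of the centre of voxel \code{[1,1,1]}, and the fixed vertical coordinate of
#' the gantry isocenter. The isocenter is a property of the scanner, not of
#' the patient, and is therefore constant across a simulated cohort.
#'
#' @slot shape integer(3), voxels per axis (vertical, lateral, longitudinal).
#' @slot spacing numeric(3), mm per voxel along each axis.
#' @slot origin numeric(3), mm coordinates of the first voxel centre.
#' @slot isocenterY numeric(1), mm vertical coordinate of the gantry isocenter.
#' @exportClass Grid3D
setClass("Grid3D",
  representation(shape = "integer", spacing = "numeric",
                 origin = "numeric", isocenterY = "numeric"))

setValidity("Grid3D", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite mm coordinates")
  if (length(object@isocenterY) != 1L || !is.finite(object@isocenterY))
    msg <- c(msg, "isocenterY must be a single finite mm value")
  if (length(msg)) msg else TRUE
})

#' Construct a Grid3D
#'
#' With \code{origin = NULL} the lattice is centred on the isocenter
#' vertically and on zero along the other two axes, which is the natural
#' frame for a simulated scanner.
#'
#' @param shape voxels per axis (vertical, lateral, longitudinal).
#' @param spacing mm per voxel per axis.
#' @param origin mm position of the first voxel centre, or \code{NULL} to
#'   centre the field of view.
#' @param isocenterY vertical mm coordinate of the gantry isocenter.
#' @return A \code{\link{Grid3D-class}} object.
#' @examples
#' g <- Grid3D(c(96, 96, 64), c(4, 4, 6))
#' gridExtent(g)
#' @export
Grid3D <- function(shape, spacing, origin = NULL, isocenterY = 0) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (is.null(origin)) {
    centre <- c(isocenterY, 0, 0)
    origin <- centre - (shape * spacing) / 2 + spacing / 2
  }
  new("Grid3D", shape = shape, spacing = spacing,
      origin = as.numeric(origin), isocenterY = as.numeric(isocenterY))
}

#' Default desk-scale grid
#'
#' 96 x 96 x 64 voxels at 4 x 4 x 6 mm (384 mm field of view per axis),
#' centred on the isocenter. Large enough to hold an adult chest phantom,
#' small enough that whole-cohort simulations run in seconds.
#' @param isocenterY vertical mm coordinate of the gantry isocenter.
#' @return A \code{\link{Grid3D-class}}.
#' @export
defaultGrid <- function(isocenterY = 0) {
  Grid3D(c(96L, 96L, 64L), c(4, 4, 6), isocenterY = isocenterY)
}

#' Parametric chest phantom description
#'
#' Ground-truth generator state for one synthetic case: an ellipsoidal body
#' with population-distributed AP/lateral diameters, two air-density
#' ellipsoidal lungs, a curved patient couch below the body, an optional
#' blanket shell draped over it, and a vertical table-height offset that
#' displaces the body centerline from the gantry isocenter (negative values
#' mean the centerline sits below the isocenter).
#'
#' @slot bodySemiAxisAP mm, vertical (anterior-posterior) body semi-axis.
#' @slot bodySemiAxisLat mm, lateral body semi-axis.
#' @slot bodyLength mm, full longitudinal body extent (ellipsoid axis).
#' @slot lungSemiAxes numeric matrix, one row per lung: (ap, lat, z) mm.
#' @slot lungCenterOffsets numeric matrix, one row per lung: offset of the
#'   lung centre from the body centre, (vertical, lateral, z) mm.
#' @slot tableHeightOffset mm, vertical displacement of the body centerline
#'   from the isocenter (positive = above the gantry centre).
#' @slot tablePresent logical, render the couch.
#' @slot blanketPresent logical, render a blanket shell over the body.
#' @slot blanketThickness mm.
#' @slot blanketGap mm, loft between skin and blanket.
#' @slot intensityLevels named numeric on a [0,1] scale:
#'   background, lung, soft, table, blanket.
#' @slot seed integer used when the spec was drawn.
#' @slot caseId character label.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(bodySemiAxisAP = "numeric", bodySemiAxisLat = "numeric",
                 bodyLength = "numeric", lungSemiAxes = "matrix",
                 lungCenterOffsets = "matrix", tableHeightOffset = "numeric",
                 tablePresent = "logical", blanketPresent = "logical",
                 blanketThickness = "numeric", blanketGap = "numeric",
                 intensityLevels = "numeric", seed = "integer",
                 caseId = "character"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@bodySemiAxisAP <= 0 || object@bodySemiAxisLat <= 0 ||
      object@bodyLength <= 0)
    msg <- c(msg, "body semi-axes and length must be positive")
  nl <- nrow(object@lungSemiAxes)
  if (nl != nrow(object@lungCenterOffsets))
    msg <- c(msg, "lungSemiAxes and lungCenterOffsets row counts differ")
  if (nl > 0 && (ncol(object@lungSemiAxes) != 3L ||
                 ncol(object@lungCenterOffsets) != 3L))
    msg <- c(msg, "lung matrices need 3 columns (ap, lat, z)")
  if (nl > 0 && any(object@lungSemiAxes <= 0))
    msg <- c(msg, "lung semi-axes must be positive")
  ## lungs fully inside the body ellipsoid: conservative sufficient condition
  ## on the circumscribing offsets (voxelized containment is checked in tests)
  if (nl > 0) {
    A <- c(object@bodySemiAxisAP, object@bodySemiAxisLat, object@bodyLength / 2)
    for (k in seq_len(nl)) {
      r <- sum(((abs(object@lungCenterOffsets[k, ]) + object@lungSemiAxes[k, ]) / A)^2)
      if (r > 1 + 1e-9)
        msg <- c(msg, sprintf("lung %d is not contained in the body ellipsoid", k))
    }
  }
  need <- c("background", "lung", "soft", "table", "blanket")
  if (!all(need %in% names(object@intensityLevels)))
    msg <- c(msg, paste("intensityLevels must name:", paste(need, collapse = ", ")))
  if (object@blanketPresent && object@blanketThickness <= 0)
    msg <- c(msg, "blanketThickness must be positive when a blanket is present")
  if (length(msg)) msg else TRUE
})

#' Default intensity levels for rendered phantoms
#'
#' Normalized-scale values chosen so the downstream thresholds separate the
#' classes: background 0.0 < lung air 0.15 < blanket 0.35 < table 0.55 <
#' soft tissue 0.7.
#' @return Named numeric vector.
#' @export
defaultIntensityLevels <- function() {
  c(background = 0.0, lung = 0.15, soft = 0.70, table = 0.55, blanket = 0.35)
}

#' Construct a chest phantom specification
#'
#' Lung geometry defaults to a symmetric two-lung template scaled to the body:
#' each lung has semi-axes (0.45, 0.26, 0.50) times the body semi-axes and is
#' offset (+0.06, +/-0.38, +0.05) of the body semi-axes from the body centre,
#' which keeps both lungs strictly inside the body ellipsoid and puts the lung
#' centerline slightly anterior of the body centerline, as in a real thorax.
#'
#' @param bodySemiAxisAP,bodySemiAxisLat mm body semi-axes (half diameters).
#' @param bodyLength mm full longitudinal extent.
#' @param tableHeightOffset mm vertical mis-centering (negative = below
#'   isocenter).
#' @param lungSemiAxes,lungCenterOffsets optional matrices (one row per lung);
#'   \code{NULL} uses the scaled template, a 0-row matrix removes the lungs.
#' @param tablePresent,blanketPresent render couch / blanket.
#' @param blanketThickness,blanketGap mm.
#' @param intensityLevels named numeric, see \code{\link{defaultIntensityLevels}}.
#' @param seed integer recorded on the spec.
#' @param caseId character label.
#' @return A \code{\link{PhantomSpec-class}}.
#' @examples
#' sp <- phantomSpec(tableHeightOffset = -12)
#' bodyDiameterAP(sp)
#' @export
phantomSpec <- function(bodySemiAxisAP = 121.5, bodySemiAxisLat = 150.5,
                        bodyLength = 300, tableHeightOffset = 0,
                        lungSemiAxes = NULL, lungCenterOffsets = NULL,
                        tablePresent = TRUE, blanketPresent = FALSE,
                        blanketThickness = 8, blanketGap = 8,
                        intensityLevels = defaultIntensityLevels(),
                        seed = NA_integer_, caseId = "case") {
  A <- c(bodySemiAxisAP, bodySemiAxisLat, bodyLength / 2)
  if (is.null(lungSemiAxes)) {
    lungSemiAxes <- rbind(c(0.45, 0.26, 0.50) * A,
                          c(0.45, 0.26, 0.50) * A)
  }
  if (is.null(lungCenterOffsets)) {
    lungCenterOffsets <- rbind(c(0.06, -0.38, 0.05) * A,
                               c(0.06, +0.38, 0.05) * A)
  }
  lungSemiAxes <- matrix(as.numeric(lungSemiAxes), ncol = 3)
  lungCenterOffsets <- matrix(as.numeric(lungCenterOffsets), ncol = 3)
  new("PhantomSpec",
      bodySemiAxisAP = as.numeric(bodySemiAxisAP),
      bodySemiAxisLat = as.numeric(bodySemiAxisLat),
      bodyLength = as.numeric(bodyLength),
      lungSemiAxes = lungSemiAxes, lungCenterOffsets = lungCenterOffsets,
      tableHeightOffset = as.numeric(tableHeightOffset),
      tablePresent = tablePresent, blanketPresent = blanketPresent,
      blanketThickness = as.numeric(blanketThickness),
      blanketGap = as.numeric(blanketGap),
      intensityLevels = intensityLevels,
      seed = as.integer(seed), caseId = as.character(caseId))
}

#' Axial 3D image with scanner-frame geometry
#'
#' @slot voxels numeric array, dim (vertical, lateral, longitudinal).
#' @slot grid \code{\link{Grid3D-class}}.
#' @slot tableHeight mm table height as recorded by the scanner, or \code{NA}.
#' @slot orientationTag "axial" or "coronal" (axis-order bookkeeping flag).
#' @exportClass Volume3D
setClass("Volume3D",
  representation(voxels = "array", grid = "Grid3D",
                 tableHeight = "numeric", orientationTag = "character"))

setValidity("Volume3D", function(object) {
  msg <- character()
  if (!identical(dim(object@voxels), as.integer(object@grid@shape)))
    msg <- c(msg, "voxel array dimensions do not match the grid shape")
  if (!object@orientationTag %in% c("axial", "coronal"))
    msg <- c(msg, "orientationTag must be 'axial' or 'coronal'")
  if (length(msg)) msg else TRUE
})

#' Construct a Volume3D
#' @param voxels numeric array matching \code{grid}.
#' @param grid a \code{\link{Grid3D-class}}.
#' @param tableHeight mm or NA.
#' @param orientationTag axis-order flag.
#' @return A \code{\link{Volume3D-class}}.
#' @export
Volume3D <- function(voxels, grid, tableHeight = NA_real_,
                     orientationTag = "axial") {
  new("Volume3D", voxels = voxels, grid = grid,
      tableHeight = as.numeric(tableHeight), orientationTag = orientationTag)
}

#' 2D anterior-posterior localizer (scout view)
#'
#' Pixels are stored with rows along the longitudinal (Z) axis and columns
#' along the lateral axis; \code{pixelSpacing} and \code{position} refer to
#' (row, column) = (Z, lateral) in mm, \code{position} being the centre of
#' pixel [1,1].
#'
#' @slot pixels numeric matrix (Z rows, lateral columns).
#' @slot pixelSpacing numeric(2) mm per pixel (Z, lateral).
#' @slot position numeric(2) mm of the first pixel centre (Z, lateral).
#' @slot sourceId scanner/centre label (e.g. "C1").
#' @slot meta list of free-form acquisition metadata (projection mode, SDD,
#'   isocenterY, ...).
#' @exportClass Localizer2D
setClass("Localizer2D",
  representation(pixels = "matrix", pixelSpacing = "numeric",
                 position = "numeric", sourceId = "character", meta = "list"))

setValidity("Localizer2D", function(object) {
  msg <- character()
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive mm values")
  if (length(object@position) != 2L)
    msg <- c(msg, "position must be two mm coordinates")
  if (length(msg)) msg else TRUE
})

#' Construct a Localizer2D
#' @param pixels matrix (Z rows, lateral columns).
#' @param pixelSpacing mm per pixel (Z, lateral).
#' @param position mm of the first pixel centre (Z, lateral).
#' @param sourceId scanner/centre label.
#' @param meta metadata list.
#' @return A \code{\link{Localizer2D-class}}.
#' @export
Localizer2D <- function(pixels, pixelSpacing, position,
                        sourceId = "sim", meta = list()) {
  new("Localizer2D", pixels = pixels, pixelSpacing = as.numeric(pixelSpacing),
      position = as.numeric(position), sourceId = as.character(sourceId),
      meta = meta)
}

#' Axis-aligned bounding box on the scanner's vertical axis
#'
#' @slot anterior mm anterior (upper) limit.
#' @slot posterior mm posterior (lower) limit; anterior > posterior on the
#'   anterior-positive axis.
#' @slot lateral numeric(2) mm lateral limits (low, high).
#' @slot zRange numeric(2) mm longitudinal limits (low, high).
#' @exportClass BoundingBox3D
setClass("BoundingBox3D",
  representation(anterior = "numeric", posterior = "numeric",
                 lateral = "numeric", zRange = "numeric"))

setValidity("BoundingBox3D", function(object) {
  msg <- character()
  if (object@anterior <= object@posterior)
    msg <- c(msg, "anterior limit must exceed posterior limit")
  if (length(object@lateral) != 2L || diff(object@lateral) < 0)
    msg <- c(msg, "lateral limits must be an increasing pair")
  if (length(object@zRange) != 2L || diff(object@zRange) < 0)
    msg <- c(msg, "zRange must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' Construct a BoundingBox3D
#' @param anterior,posterior mm vertical limits.
#' @param lateral mm pair.
#' @param zRange mm pair.
#' @return A \code{\link{BoundingBox3D-class}}.
#' @export
BoundingBox3D <- function(anterior, posterior, lateral, zRange) {
  new("BoundingBox3D", anterior = as.numeric(anterior),
      posterior = as.numeric(posterior), lateral = as.numeric(lateral),
      zRange = as.numeric(zRange))
}

#' Body/lung centerline measurement for one volume
#'
#' The centerline is by definition the vertical midpoint of the bounding box,
#' \code{(anterior + posterior)/2}; the validity method enforces this exactly.
#'
#' @slot bodyCenterline mm (BCGTH or BCDL depending on \code{source}).
#' @slot lungCenterline mm, or \code{NA} when no lung was found.
#' @slot bodyBBox \code{\link{BoundingBox3D-class}}.
#' @slot lungBBox \code{BoundingBox3D} or \code{NULL}.
#' @slot perSliceCenterlines numeric per-slice body centerlines (mm, along Z)
#'   or \code{NULL}.
#' @slot truncated logical, body touches the field-of-view border.
#' @slot lungFallback logical, fewer than two lung components were found.
#' @slot source "ground_truth" or "predicted".
#' @slot isocenterY mm gantry isocenter of the measurement frame.
#' @slot caseId character label.
#' @exportClass CenterlineReport
setClass("CenterlineReport",
  representation(bodyCenterline = "numeric", lungCenterline = "numeric",
                 bodyBBox = "BoundingBox3D", lungBBox = "ANY",
                 perSliceCenterlines = "ANY", truncated = "logical",
                 lungFallback = "logical", source = "character",
                 isocenterY = "numeric", caseId = "character"))

setValidity("CenterlineReport", function(object) {
  msg <- character()
  mid <- (object@bodyBBox@anterior + object@bodyBBox@posterior) / 2
  if (!isTRUE(all.equal(object@bodyCenterline, mid, tolerance = 0)))
    msg <- c(msg, "bodyCenterline must equal the body bounding-box midpoint")
  if (!is.null(object@lungBBox) && is.finite(object@lungCenterline)) {
    lmid <- (object@lungBBox@anterior + object@lungBBox@posterior) / 2
    if (!isTRUE(all.equal(object@lungCenterline, lmid, tolerance = 0)))
      msg <- c(msg, "lungCenterline must equal the lung bounding-box midpoint")
  }
  if (!object@source %in% c("ground_truth", "predicted"))
    msg <- c(msg, "source must be 'ground_truth' or 'predicted'")
  if (length(msg)) msg else TRUE
})

#' Preprocessed localizer/volume pair for network training
#'
#' @slot localizerIn numeric matrix (lateral x Z), intensities in [0,1].
#' @slot volumeOut numeric array (AP x lateral x Z), intensities in [0,1],
#'   coronal-resized target volume.
#' @slot cropRecord list of mm extents retained per axis (\code{ap},
#'   \code{lat}, \code{z}, each c(low, high)) plus \code{isocenterY}; used to
#'   map predictions back to the scanner frame.
#' @exportClass TrainingPair
setClass("TrainingPair",
  representation(localizerIn = "matrix", volumeOut = "array",
                 cropRecord = "list"))

setValidity("TrainingPair", function(object) {
  msg <- character()
  rng <- range(object@localizerIn, object@volumeOut)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "intensities must lie in [0,1]")
  cr <- object@cropRecord
  for (ax in c("ap", "lat", "z")) {
    if (is.null(cr[[ax]]) || length(cr[[ax]]) != 2L || diff(cr[[ax]]) <= 0) {
      msg <- c(msg, "cropRecord must hold positive mm extents for ap/lat/z")
      break
    }
  }
  if (length(msg)) msg else TRUE
})
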