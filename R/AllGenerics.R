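## Generics, accessors and show methods. Slots are never touched directly by
## user code; everything goes through these.

#' @name accessors
#' @title Accessors for ctcenterline data objects
#' @param x,object an object.
#' @param axis 1 (vertical), 2 (lateral) or 3 (longitudinal).
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "Volume3D", function(x) x@voxels)

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Localizer2D", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("grid3d", function(x) standardGeneric("grid3d"))
#' @rdname accessors
#' @export
setMethod("grid3d", "Volume3D", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setMethod("gridShape", "Grid3D", function(x) x@shape)

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setMethod("gridSpacing", "Grid3D", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "Volume3D", function(x) x@grid@spacing)

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setMethod("gridOrigin", "Grid3D", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("isocenterY", function(x) standardGeneric("isocenterY"))
#' @rdname accessors
#' @export
setMethod("isocenterY", "Grid3D", function(x) x@isocenterY)
#' @rdname accessors
#' @export
setMethod("isocenterY", "Volume3D", function(x) x@grid@isocenterY)
#' @rdname accessors
#' @export
setMethod("isocenterY", "CenterlineReport", function(x) x@isocenterY)

#' Voxel-centre coordinates along one axis
#' @param grid a \code{\link{Grid3D-class}}.
#' @param axis 1 (vertical), 2 (lateral) or 3 (longitudinal).
#' @return Numeric vector of mm coordinates.
#' @export
axisCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1) * grid@spacing[axis]
}

#' Physical extent of a grid (outer voxel faces)
#' @param grid a \code{\link{Grid3D-class}}.
#' @return 3 x 2 matrix of mm (low, high) per axis.
#' @export
gridExtent <- function(grid) {
  lo <- grid@origin - grid@spacing / 2
  hi <- grid@origin + (grid@shape - 0.5) * grid@spacing
  m <- cbind(low = lo, high = hi)
  rownames(m) <- c("vertical", "lateral", "longitudinal")
  m
}

#' Physical extent of a localizer (outer pixel edges)
#' @param localizer a \code{\link{Localizer2D-class}}.
#' @return 2 x 2 matrix of mm (low, high) for (Z, lateral).
#' @export
localizerExtent <- function(localizer) {
  n <- dim(localizer@pixels)
  lo <- localizer@position - localizer@pixelSpacing / 2
  hi <- localizer@position + (n - 0.5) * localizer@pixelSpacing
  m <- cbind(low = lo, high = hi)
  rownames(m) <- c("longitudinal", "lateral")
  m
}

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setMethod("sourceId", "Localizer2D", function(x) x@sourceId)

#' @rdname accessors
#' @export
setGeneric("bodyDiameterAP", function(x) standardGeneric("bodyDiameterAP"))
#' @rdname accessors
#' @export
setMethod("bodyDiameterAP", "PhantomSpec", function(x) 2 * x@bodySemiAxisAP)

#' @rdname accessors
#' @export
setGeneric("bodyDiameterLat", function(x) standardGeneric("bodyDiameterLat"))
#' @rdname accessors
#' @export
setMethod("bodyDiameterLat", "PhantomSpec", function(x) 2 * x@bodySemiAxisLat)

#' @rdname accessors
#' @export
setGeneric("tableHeightOffset", function(x) standardGeneric("tableHeightOffset"))
#' @rdname accessors
#' @export
setMethod("tableHeightOffset", "PhantomSpec", function(x) x@tableHeightOffset)

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setMethod("caseId", "PhantomSpec", function(x) x@caseId)
#' @rdname accessors
#' @export
setMethod("caseId", "CenterlineReport", function(x) x@caseId)

#' @rdname accessors
#' @export
setGeneric("bodyCenterline", function(x) standardGeneric("bodyCenterline"))
#' @rdname accessors
#' @export
setMethod("bodyCenterline", "CenterlineReport", function(x) x@bodyCenterline)

#' @rdname accessors
#' @export
setGeneric("lungCenterline", function(x) standardGeneric("lungCenterline"))
#' @rdname accessors
#' @export
setMethod("lungCenterline", "CenterlineReport", function(x) x@lungCenterline)

#' @rdname accessors
#' @export
setGeneric("bodyBBox", function(x) standardGeneric("bodyBBox"))
#' @rdname accessors
#' @export
setMethod("bodyBBox", "CenterlineReport", function(x) x@bodyBBox)

#' @rdname accessors
#' @export
setGeneric("lungBBox", function(x) standardGeneric("lungBBox"))
#' @rdname accessors
#' @export
setMethod("lungBBox", "CenterlineReport", function(x) x@lungBBox)

#' @rdname accessors
#' @export
setGeneric("isTruncated", function(x) standardGeneric("isTruncated"))
#' @rdname accessors
#' @export
setMethod("isTruncated", "CenterlineReport", function(x) x@truncated)

#' Vertical midpoint of a bounding box
#' @param x a \code{\link{BoundingBox3D-class}}.
#' @return mm centerline position.
#' @export
setGeneric("centerline", function(x) standardGeneric("centerline"))
#' @rdname centerline
#' @export
setMethod("centerline", "BoundingBox3D",
          function(x) (x@anterior + x@posterior) / 2)

#' @rdname accessors
#' @export
setGeneric("cropRecord", function(x) standardGeneric("cropRecord"))
#' @rdname accessors
#' @export
setMethod("cropRecord", "TrainingPair", function(x) x@cropRecord)

#' @rdname accessors
#' @export
setGeneric("localizerIn", function(x) standardGeneric("localizerIn"))
#' @rdname accessors
#' @export
setMethod("localizerIn", "TrainingPair", function(x) x@localizerIn)

#' @rdname accessors
#' @export
setGeneric("volumeOut", function(x) standardGeneric("volumeOut"))
#' @rdname accessors
#' @export
setMethod("volumeOut", "TrainingPair", function(x) x@volumeOut)

setMethod("show", "Grid3D", function(object) {
  cat(sprintf("Grid3D: %s voxels @ %s mm, isocenterY = %g mm\n",
              paste(object@shape, collapse = " x "),
              paste(format(object@spacing), collapse = " x "),
              object@isocenterY))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec '%s': D_AP %.1f mm, D_Lat %.1f mm, length %.0f mm\n",
    "  offset %+.1f mm vs isocenter; lungs: %d; table: %s; blanket: %s\n"),
    object@caseId, 2 * object@bodySemiAxisAP, 2 * object@bodySemiAxisLat,
    object@bodyLength, object@tableHeightOffset, nrow(object@lungSemiAxes),
    object@tablePresent, object@blanketPresent))
})

setMethod("show", "Volume3D", function(object) {
  cat(sprintf("Volume3D (%s): %s voxels, range [%.3g, %.3g]\n",
              object@orientationTag,
              paste(dim(object@voxels), collapse = " x "),
              min(object@voxels), max(object@voxels)))
  show(object@grid)
})

setMethod("show", "Localizer2D", function(object) {
  cat(sprintf("Localizer2D [%s]: %d x %d pixels (Z x lateral) @ %s mm\n",
              object@sourceId, nrow(object@pixels), ncol(object@pixels),
              paste(format(object@pixelSpacing), collapse = " x ")))
})

setMethod("show", "BoundingBox3D", function(object) {
  cat(sprintf(
    "BoundingBox3D: vertical [%.1f, %.1f], lateral [%.1f, %.1f], z [%.1f, %.1f] mm\n",
    object@posterior, object@anterior, object@lateral[1], object@lateral[2],
    object@zRange[1], object@zRange[2]))
})

setMethod("show", "CenterlineReport", function(object) {
  cat(sprintf(paste0(
    "CenterlineReport '%s' (%s):\n",
    "  body centerline %+.2f mm, lung centerline %s mm (vs isocenter %g)\n",
    "  truncated: %s, lung fallback: %s\n"),
    object@caseId, object@source, object@bodyCenterline,
    ifelse(is.finite(object@lungCenterline),
           sprintf("%+.2f", object@lungCenterline), "NA"),
    object@isocenterY, object@truncated, object@lungFallback))
})

setMethod("show", "TrainingPair", function(object) {
  cat(sprintf("TrainingPair: localizer %s, volume %s (AP x lat x Z)\n",
              paste(dim(object@localizerIn), collapse = " x "),
              paste(dim(object@volumeOut), collapse = " x ")))
})
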