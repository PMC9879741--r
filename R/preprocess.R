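## Image pre-processing: crop localizer and volume to a common physical
## extent using their position metadata, min-max normalize to [0,1], resize
## to the fixed training matrices, and split cohorts per scanner.
## Full-scale defaults: localizer 144 (lateral) x 64 (Z); coronal volume
## 184 (AP) x 144 (lateral) x 64 (Z). Desk-scale shapes are plain arguments.

#' Crop a localizer/volume pair to their common physical extent
#'
#' Both images are restricted to the intersection of their lateral and
#' longitudinal mm extents (voxel/pixel centres inside the intersection);
#' the retained mm extents are recorded so a prediction can be mapped back
#' into the scanner frame.
#'
#' @param localizer a \code{\link{Localizer2D-class}}.
#' @param volume a \code{\link{Volume3D-class}} (axial).
#' @return List with elements \code{localizer}, \code{volume},
#'   \code{cropRecord} (mm extents \code{ap}, \code{lat}, \code{z} of the
#'   cropped volume, plus \code{isocenterY} and \code{sourceId}).
#' @export
cropToCommonExtent <- function(localizer, volume) {
  g <- volume@grid
  ve <- gridExtent(g)
  le <- localizerExtent(localizer)
  latInt <- intersectInterval(ve[2, ], le[2, ])
  zInt <- intersectInterval(ve[3, ], le[1, ])
  if (is.null(latInt) || is.null(zInt))
    stop("localizer and volume extents do not overlap")
  xs <- axisCoords(g, 2); zs <- axisCoords(g, 3)
  ix <- which(xs >= latInt[1] & xs <= latInt[2])
  iz <- which(zs >= zInt[1] & zs <= zInt[2])
  if (!length(ix) || !length(iz)) stop("empty crop on the volume grid")
  newGrid <- Grid3D(c(g@shape[1], length(ix), length(iz)), g@spacing,
                    origin = c(g@origin[1], xs[ix[1]], zs[iz[1]]),
                    isocenterY = g@isocenterY)
  volC <- Volume3D(volume@voxels[, ix, iz, drop = FALSE], newGrid,
                   tableHeight = volume@tableHeight)

  lz <- localizer@position[1] +
    (seq_len(nrow(localizer@pixels)) - 1) * localizer@pixelSpacing[1]
  lx <- localizer@position[2] +
    (seq_len(ncol(localizer@pixels)) - 1) * localizer@pixelSpacing[2]
  jz <- which(lz >= zInt[1] & lz <= zInt[2])
  jx <- which(lx >= latInt[1] & lx <= latInt[2])
  if (!length(jz) || !length(jx)) stop("empty crop on the localizer")
  locC <- Localizer2D(localizer@pixels[jz, jx, drop = FALSE],
                      pixelSpacing = localizer@pixelSpacing,
                      position = c(lz[jz[1]], lx[jx[1]]),
                      sourceId = localizer@sourceId, meta = localizer@meta)
  ext <- gridExtent(newGrid)
  list(localizer = locC, volume = volC,
       cropRecord = list(ap = unname(ext[1, ]), lat = unname(ext[2, ]),
                         z = unname(ext[3, ]), isocenterY = g@isocenterY,
                         sourceId = localizer@sourceId))
}

#' Min-max normalize intensities to [0, 1]
#'
#' Affine rescaling with min -> 0 and max -> 1. A constant image cannot be
#' rescaled; it becomes all zeros with a warning.
#'
#' @param x numeric array/matrix, \code{\link{Localizer2D-class}} or
#'   \code{\link{Volume3D-class}}.
#' @return Same shape/class as the input.
#' @examples
#' normalize01(c(0, 5, 10))
#' @export
setGeneric("normalize01", function(x) standardGeneric("normalize01"))

#' @rdname normalize01
#' @export
setMethod("normalize01", "ANY", function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite intensities")
  if (rng[1] == rng[2]) {
    warning("constant image: normalize01 returns zeros")
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
})

#' @rdname normalize01
#' @export
setMethod("normalize01", "Localizer2D", function(x) {
  x@pixels <- callNextMethod(x@pixels)
  x
})

#' @rdname normalize01
#' @export
setMethod("normalize01", "Volume3D", function(x) {
  x@voxels <- callNextMethod(x@voxels)
  x
})

#' Resize a localizer to the network input matrix
#'
#' Output axes are (lateral, Z); the full-scale default is 144 x 64.
#' Linear interpolation, values clamped to [0,1].
#'
#' @param localizer a \code{\link{Localizer2D-class}} or a (Z x lateral)
#'   matrix.
#' @param targetShape c(lateral, Z) pixel counts.
#' @return Numeric matrix of dim \code{targetShape}.
#' @export
resizeLocalizer <- function(localizer, targetShape = c(144L, 64L)) {
  p <- if (is(localizer, "Localizer2D")) localizer@pixels else localizer
  out <- resizeArray(t(p), as.integer(targetShape))   # -> (lateral, Z)
  clamp01(out)
}

#' Reorient an axial volume to coronal and resize to the training matrix
#'
#' The package stores axial volumes as (AP, lateral, Z); the coronal view is
#' the same array read slice-by-slice along AP, so the reorientation is a
#' pure axis interpretation (recorded in the result's \code{orientation}
#' attribute) and the resize is a separable linear interpolation to the
#' target matrix, 184 x 144 x 64 (AP x lateral x Z) at full scale.
#'
#' @param volume a \code{\link{Volume3D-class}} or (AP, lateral, Z) array.
#' @param targetShape c(AP, lateral, Z) voxel counts.
#' @return Numeric array of dim \code{targetShape}, values in [0,1],
#'   attribute \code{orientation = "coronal"}.
#' @export
resizeVolumeCoronal <- function(volume, targetShape = c(184L, 144L, 64L)) {
  v <- if (is(volume, "Volume3D")) volume@voxels else volume
  out <- clamp01(resizeArray(v, as.integer(targetShape)))
  attr(out, "orientation") <- "coronal"
  out
}

#' Assemble one preprocessed training pair
#'
#' crop -> normalize -> resize, keeping the mm bookkeeping needed to invert
#' predictions back into the scanner frame.
#'
#' @param localizer a \code{\link{Localizer2D-class}}.
#' @param volume the matching \code{\link{Volume3D-class}}.
#' @param locShape c(lateral, Z) input matrix.
#' @param volShape c(AP, lateral, Z) output matrix.
#' @return A \code{\link{TrainingPair-class}}.
#' @export
makeTrainingPair <- function(localizer, volume,
                             locShape = c(144L, 64L),
                             volShape = c(184L, 144L, 64L)) {
  cr <- cropToCommonExtent(localizer, volume)
  locIn <- resizeLocalizer(normalize01(cr$localizer), locShape)
  volOut <- resizeVolumeCoronal(normalize01(cr$volume), volShape)
  new("TrainingPair", localizerIn = locIn, volumeOut = volOut,
      cropRecord = cr$cropRecord)
}

#' Reconstruct the scanner-frame grid of a prediction
#'
#' Maps a network output of shape \code{outShape} onto the mm extents stored
#' in a crop record, so bounding boxes measured on the prediction are in the
#' same frame (and isocenter) as the ground truth.
#'
#' @param cropRecord crop record from \code{\link{cropToCommonExtent}}.
#' @param outShape c(AP, lateral, Z) voxel counts of the prediction.
#' @return A \code{\link{Grid3D-class}}.
#' @export
predictionGrid <- function(cropRecord, outShape) {
  outShape <- as.integer(outShape)
  ext <- rbind(cropRecord$ap, cropRecord$lat, cropRecord$z)
  spacing <- (ext[, 2] - ext[, 1]) / outShape
  Grid3D(outShape, spacing, origin = ext[, 1] + spacing / 2,
         isocenterY = cropRecord$isocenterY)
}

#' Split a cohort into training and test sets, stratified by scanner
#'
#' Deterministic under a fixed seed; per source the split is exhaustive and
#' disjoint with round(fraction * n) training cases.
#'
#' @param sourceIds character vector, one scanner/centre label per case.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @examples
#' splitCohort(rep("C1", 10), seed = 1)
#' @export
splitCohort <- function(sourceIds, fraction = 0.8, seed = 1) {
  n <- length(sourceIds)
  if (n < 2) stop("need at least two cases to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(as.integer(seed))
  train <- integer(0)
  for (src in unique(sourceIds)) {
    idx <- which(sourceIds == src)
    nTr <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
    train <- c(train, sort(sample(idx, nTr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}
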