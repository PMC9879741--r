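## Centerline measurement: body segmentation by intensity thresholding plus
## region shape evaluation (the couch and loose objects such as blankets are
## rejected by aspect ratio and projected solidity, not by intensity alone),
## lung segmentation inside the body, axis-aligned bounding boxes, and the
## vertical centerline = bounding-box midpoint. All thresholds act on the
## min-max normalized volume, so measurements are invariant to affine
## intensity rescaling.

componentStats <- function(labels, compId, grid) {
  d <- dim(labels)
  comp <- labels == compId
  spy <- grid@spacing[1]; spx <- grid@spacing[2]
  ## project along Z once; everything else derives from the 2-D footprint
  proj <- matrix(rowSums(matrix(comp, d[1] * d[2], d[3])) > 0, d[1], d[2])
  idx2 <- which(proj, arr.ind = TRUE)
  heightMm <- (diff(range(idx2[, 1])) + 1) * spy
  widthMm <- (diff(range(idx2[, 2])) + 1) * spx
  ## projected (vertical x lateral) solidity: pixel area over convex hull area
  area <- nrow(idx2) * spy * spx
  solidity <- 1
  if (nrow(idx2) >= 3) {
    pts <- cbind(idx2[, 1] * spy, idx2[, 2] * spx)
    h <- grDevices::chull(pts)
    hp <- pts[h, , drop = FALSE]
    nh <- nrow(hp)
    hullArea <- abs(sum(hp[, 1] * hp[c(2:nh, 1), 2] -
                          hp[c(2:nh, 1), 1] * hp[, 2])) / 2
    if (hullArea > 0) solidity <- min(1, area / hullArea)
  }
  list(size = sum(comp), aspect = widthMm / heightMm, solidity = solidity)
}

fillHoles <- function(mask) {
  bg <- !mask
  lab <- cpp_label3d(bg, 6L)
  d <- dim(mask)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0]
  outside <- lab %in% border
  dim(outside) <- d
  mask | (bg & !outside)
}

erode6 <- function(m) {
  out <- cpp_erode6(m)
  storage.mode(out) <- "logical"
  out
}

dilate6 <- function(m) {
  out <- cpp_dilate6(m)
  storage.mode(out) <- "logical"
  out
}

## Vertical-occupancy waist split. On a soft, reconstructed volume the couch
## can fuse with the body across the blurred air gap; the fused region shows
## a characteristic valley ("waist") in the per-level voxel count between the
## body lobe above and the flat couch lobe below. When both neighbouring
## lobes exceed waistRatio times the valley occupancy, the mask is cut at
## the valley and the shape rules re-applied to the parts. A clean body mask
## has a unimodal vertical profile, so this is a no-op on ground truth.
waistSplit <- function(mask, waistRatio = 1.5) {
  d <- dim(mask)
  occ <- rowSums(matrix(mask, d[1], d[2] * d[3]))
  lv <- which(occ > 0)
  if (length(lv) < 5) return(NULL)
  lo <- min(lv); hi <- max(lv)
  inner <- (lo + 1):(hi - 1)
  below <- cummax(occ[lo:hi])[inner - lo]        # max occupancy below level i
  above <- rev(cummax(rev(occ[lo:hi])))[inner - lo + 2]
  cand <- inner[below > waistRatio * occ[inner] &
                  above > waistRatio * occ[inner]]
  if (!length(cand)) return(NULL)
  cand[which.min(occ[cand])]
}

#' Segment the patient body in an axial volume
#'
#' Thresholds the min-max normalized volume, labels connected components
#' (26-neighbourhood) and keeps the largest component that passes the region
#' shape rules: lateral-width / vertical-height ratio at most
#' \code{maxAspect} (rejects the couch, a wide flat slab) and projected
#' solidity at least \code{minSolidity} (rejects thin curved shells such as
#' blankets and the couch cradle). A component whose vertical occupancy
#' profile shows a couch-like waist is split at the waist and re-evaluated,
#' which removes a couch that has fused to the body across a blurred air gap
#' (common on reconstructed volumes). Interior holes -- the air-density
#' lungs -- are filled so the body mask is solid.
#'
#' @param volume a \code{\link{Volume3D-class}}.
#' @param bodyThreshold normalized intensity threshold (default 0.25).
#' @param maxAspect,minSolidity region shape rules.
#' @return Logical array body mask (attribute \code{"nComponents"} reports
#'   how many above-threshold components existed).
#' @examples
#' vol <- renderVolume(phantomSpec(), defaultGrid())
#' mask <- segmentBody(vol)
#' @export
segmentBody <- function(volume, bodyThreshold = 0.25, maxAspect = 4,
                        minSolidity = 0.5) {
  v <- normalize01(volume@voxels)
  mask <- v >= bodyThreshold
  if (!any(mask)) stop("no body found: nothing above the threshold")
  pickComponent <- function(labels) {
    sizes <- tabulate(labels[labels > 0])
    for (comp in order(sizes, decreasing = TRUE)) {
      st <- componentStats(labels, comp, volume@grid)
      if (st$aspect <= maxAspect && st$solidity >= minSolidity)
        return(comp)
    }
    0L
  }
  ## bounding-box extremes are max statistics: a level supported by almost
  ## no voxels is reconstruction fuzz, not anatomy
  trimSparseLevels <- function(m, minLevelVoxels = 16L) {
    d <- dim(m)
    occ <- rowSums(matrix(m, d[1], d[2] * d[3]))
    lv <- which(occ > 0)
    if (!length(lv)) return(m)
    lo <- min(lv); hi <- max(lv)
    while (lo < hi && occ[lo] < minLevelVoxels) { m[lo, , ] <- FALSE; lo <- lo + 1 }
    while (hi > lo && occ[hi] < minLevelVoxels) { m[hi, , ] <- FALSE; hi <- hi - 1 }
    m
  }
  ## Selection runs on the eroded mask: erosion shreds porous reconstruction
  ## fuzz and breaks the thin partial-volume welds that attach blankets or a
  ## blur-fused couch to the body. Two conditional dilations afterwards
  ## restore the exact pre-erosion boundary on a clean mask (and the typical
  ## blur depth of a reconstructed surface on a soft one) without crossing
  ## the re-opened gaps.
  core <- erode6(mask)
  if (!any(core)) core <- mask
  relab <- cpp_label3d(core, 26L)
  nComp <- max(relab)
  chosen <- pickComponent(relab)
  if (chosen == 0L) stop("no body found: no component passes the shape rules")
  body <- relab == chosen
  cut <- waistSplit(body)
  if (!is.null(cut) && cut > 1L) {
    ## the valley level itself is kept with the body: the true posterior
    ## skin sits inside the blurred gap, so assigning the valley to the
    ## couch would bias the posterior limit anteriorly
    split <- body
    split[seq_len(cut - 1L), , ] <- FALSE
    relab2 <- cpp_label3d(split, 26L)
    again <- pickComponent(relab2)
    if (again > 0L) body <- relab2 == again
  }
  for (k in 1:2) body <- dilate6(body) & mask
  body <- trimSparseLevels(body)
  body <- fillHoles(body)
  attr(body, "nComponents") <- nComp
  body
}

#' Segment the lungs inside a body mask
#'
#' Low-intensity voxels inside the body are labelled and the two largest
#' components kept. With fewer than two candidates the result is flagged as
#' a fallback (single component) or empty (lungless volume) with a warning.
#'
#' @param volume a \code{\link{Volume3D-class}}.
#' @param bodyMask logical array from \code{\link{segmentBody}}.
#' @param lungThreshold normalized intensity below which a voxel counts as
#'   lung air (default 0.45, between normalized lung air and soft tissue).
#' @param minVoxels discard candidate components smaller than this.
#' @return Logical lung mask with attributes \code{"fallback"} (logical) and
#'   \code{"nLungs"}.
#' @export
segmentLungs <- function(volume, bodyMask, lungThreshold = 0.45,
                         minVoxels = 8L) {
  v <- normalize01(volume@voxels)
  ## search the body interior: the partial-volume shell at the skin dips
  ## below any threshold and is not lung
  cand <- erode6(bodyMask) & (v < lungThreshold)
  labels <- cpp_label3d(cand, 26L)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= minVoxels)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  fallback <- length(keep) < 2L
  if (fallback)
    warning(sprintf("lung segmentation found %d component(s); flagged",
                    length(keep)))
  keep <- utils::head(keep, 2L)
  lungs <- labels %in% keep & labels > 0L
  dim(lungs) <- dim(bodyMask)
  attr(lungs, "fallback") <- fallback
  attr(lungs, "nLungs") <- length(keep)
  lungs
}

#' Bounding box and vertical centerline of a mask
#'
#' The axis-aligned box over the mask voxels (outer voxel faces, mm), the
#' centerline being its vertical midpoint. An optional longitudinal scan
#' range restricts the box to the slices whose centres fall inside it,
#' mirroring how the centerline depends on the selected scan range.
#'
#' @param mask logical array.
#' @param grid the \code{\link{Grid3D-class}} the mask lives on.
#' @param scanRange optional c(z0, z1) mm.
#' @return List with \code{bbox} (\code{\link{BoundingBox3D-class}}) and
#'   \code{centerline} (mm).
#' @export
bboxAndCenterline <- function(mask, grid, scanRange = NULL) {
  zc <- axisCoords(grid, 3)
  zsel <- seq_along(zc)
  if (!is.null(scanRange)) {
    zsel <- which(zc >= scanRange[1] & zc <= scanRange[2])
    if (!length(zsel)) stop("scan range contains no slices")
  }
  sub <- mask[, , zsel, drop = FALSE]
  if (!any(sub)) stop("empty mask within the scan range")
  idx <- which(sub, arr.ind = TRUE)
  y <- axisCoords(grid, 1); x <- axisCoords(grid, 2)
  sp <- grid@spacing
  bbox <- BoundingBox3D(
    anterior = max(y[idx[, 1]]) + sp[1] / 2,
    posterior = min(y[idx[, 1]]) - sp[1] / 2,
    lateral = c(min(x[idx[, 2]]) - sp[2] / 2, max(x[idx[, 2]]) + sp[2] / 2),
    zRange = c(min(zc[zsel[idx[, 3]]]) - sp[3] / 2,
               max(zc[zsel[idx[, 3]]]) + sp[3] / 2))
  list(bbox = bbox, centerline = centerline(bbox))
}

#' Detect field-of-view truncation of the body
#'
#' TRUE when the mask touches a lateral or vertical volume boundary on more
#' than \code{fraction} of the slices that contain mask voxels (strict
#' inequality: \code{fraction = 0} flags any touch).
#'
#' @param bodyMask logical array.
#' @param grid matching \code{\link{Grid3D-class}} (shape bookkeeping only).
#' @param fraction tolerated touching-slice fraction.
#' @return Logical flag.
#' @export
detectTruncation <- function(bodyMask, grid, fraction = 0.05) {
  d <- dim(bodyMask)
  occupied <- colSums(matrix(bodyMask, d[1] * d[2], d[3])) > 0
  touching <- colSums(matrix(bodyMask[1, , ], d[2], d[3])) +
    colSums(matrix(bodyMask[d[1], , ], d[2], d[3])) +
    colSums(matrix(bodyMask[, 1, ], d[1], d[3])) +
    colSums(matrix(bodyMask[, d[2], ], d[1], d[3])) > 0
  if (!any(occupied)) return(FALSE)
  mean(touching[occupied]) > fraction
}

#' Measure body and lung centerlines of one volume
#'
#' Full measurement pipeline: body segmentation with couch/object removal,
#' truncation flag, lung segmentation, one joint bounding box over both
#' lungs, and (optionally) per-slice body centerlines along Z.
#'
#' @param volume a \code{\link{Volume3D-class}} (ground truth or predicted).
#' @param bodyThreshold,lungThreshold normalized-intensity thresholds.
#' @param scanRange optional c(z0, z1) mm restriction for the boxes.
#' @param perSlice also compute per-slice body centerlines.
#' @param source "ground_truth" or "predicted".
#' @param caseId label carried into the report.
#' @return A \code{\link{CenterlineReport-class}}.
#' @examples
#' vol <- renderVolume(phantomSpec(tableHeightOffset = -12), defaultGrid())
#' measureCenterlines(vol)
#' @export
measureCenterlines <- function(volume, bodyThreshold = 0.25,
                               lungThreshold = 0.45, scanRange = NULL,
                               perSlice = FALSE, source = "ground_truth",
                               caseId = "case") {
  body <- segmentBody(volume, bodyThreshold)
  truncated <- detectTruncation(body, volume@grid)
  lungs <- withCallingHandlers(
    segmentLungs(volume, body, lungThreshold),
    warning = function(w) invokeRestart("muffleWarning"))
  bodyBC <- bboxAndCenterline(body, volume@grid, scanRange)
  lungFallback <- attr(lungs, "fallback")
  if (any(lungs)) {
    lungBC <- bboxAndCenterline(lungs, volume@grid, scanRange)
    lungCl <- lungBC$centerline
    lungBox <- lungBC$bbox
  } else {
    lungCl <- NA_real_
    lungBox <- NULL
  }
  psc <- NULL
  if (perSlice) {
    y <- axisCoords(volume@grid, 1)
    sp <- volume@grid@spacing[1]
    psc <- apply(body, 3, function(s) {
      rows <- which(rowSums(s) > 0)
      if (!length(rows)) return(NA_real_)
      (max(y[rows]) + min(y[rows])) / 2
    })
  }
  new("CenterlineReport",
      bodyCenterline = bodyBC$centerline, lungCenterline = lungCl,
      bodyBBox = bodyBC$bbox, lungBBox = lungBox,
      perSliceCenterlines = psc, truncated = truncated,
      lungFallback = lungFallback, source = source,
      isocenterY = volume@grid@isocenterY, caseId = caseId)
}
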