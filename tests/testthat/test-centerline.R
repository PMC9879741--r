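test_that("body mask matches the analytic ellipsoid (IoU >= 0.95)", {
  g <- defaultGrid()
  sp <- phantomSpec(tableHeightOffset = -6, tablePresent = FALSE)
  vol <- renderVolume(sp, g)
  mask <- segmentBody(vol)
  y <- axisCoords(g, 1); x <- axisCoords(g, 2); z <- axisCoords(g, 3)
  f <- outer(outer(((y + 6) / 121.5)^2, (x / 150.5)^2, "+"), (z / 150)^2, "+")
  ana <- f <= 1
  expect_gte(sum(mask & ana) / sum(mask | ana), 0.95)
})

test_that("couch voxels are excluded from the body mask", {
  g <- defaultGrid()
  spT <- phantomSpec(tableHeightOffset = 2)
  spN <- phantomSpec(tableHeightOffset = 2, tablePresent = FALSE)
  volT <- renderVolume(spT, g)
  volN <- renderVolume(spN, g)
  tableRegion <- abs(voxels(volT) - voxels(volN)) > 1e-6
  expect_true(any(tableRegion))
  mask <- segmentBody(volT)
  expect_identical(sum(mask & tableRegion), 0L)
})

test_that("a blanket shifts the measured body centerline by less than a voxel", {
  g <- defaultGrid()
  base <- phantomSpec(tableHeightOffset = -4)
  wrapped <- phantomSpec(tableHeightOffset = -4, blanketPresent = TRUE)
  c0 <- bodyCenterline(measureCenterlines(renderVolume(base, g)))
  c1 <- bodyCenterline(measureCenterlines(renderVolume(wrapped, g)))
  expect_lt(abs(c1 - c0), gridSpacing(g)[1])
})

test_that("lung segmentation finds two lungs at the specified centres", {
  g <- defaultGrid()
  sp <- phantomSpec(tableHeightOffset = 8)
  vol <- renderVolume(sp, g)
  body <- segmentBody(vol)
  lungs <- segmentLungs(vol, body)
  expect_false(attr(lungs, "fallback"))
  expect_identical(attr(lungs, "nLungs"), 2L)
  lab <- ctcenterline:::cpp_label3d(lungs, 26L)
  for (k in 1:2) {
    idx <- which(lab == k, arr.ind = TRUE)
    cen <- c(mean(axisCoords(g, 1)[idx[, 1]]),
             mean(axisCoords(g, 2)[idx[, 2]]),
             mean(axisCoords(g, 3)[idx[, 3]]))
    truth <- rbind(c(8, 0, 0) + sp@lungCenterOffsets[1, ],
                   c(8, 0, 0) + sp@lungCenterOffsets[2, ])
    best <- min(sqrt(rowSums(sweep(truth, 2, cen)^2)))
    expect_lt(best, max(gridSpacing(g)))
  }
})

test_that("a lungless phantom is flagged as a fallback", {
  g <- tinyGrid()
  sp <- tinySpec(lungSemiAxes = matrix(numeric(0), 0, 3),
                 lungCenterOffsets = matrix(numeric(0), 0, 3))
  vol <- renderVolume(sp, g)
  body <- segmentBody(vol)
  expect_warning(lungs <- segmentLungs(vol, body), "flagged")
  expect_true(attr(lungs, "fallback"))
  rep <- measureCenterlines(vol)
  expect_true(rep@lungFallback)
  expect_true(is.na(lungCenterline(rep)))
})

test_that("left-right mirroring leaves the lung centerline unchanged", {
  g <- tinyGrid()
  sp <- tinySpec(5)
  mir <- tinySpec(5,
                  lungSemiAxes = sp@lungSemiAxes[2:1, ],
                  lungCenterOffsets = sp@lungCenterOffsets[2:1, ] *
                    matrix(rep(c(1, -1, 1), each = 2), 2))
  r1 <- measureCenterlines(renderVolume(sp, g))
  r2 <- measureCenterlines(renderVolume(mir, g))
  expect_equal(lungCenterline(r1), lungCenterline(r2))
})

test_that("a single-voxel mask gives a degenerate box at that voxel centre", {
  g <- tinyGrid()
  mask <- array(FALSE, dim = gridShape(g))
  mask[10, 12, 5] <- TRUE
  bc <- bboxAndCenterline(mask, g)
  expect_equal(bc$centerline, axisCoords(g, 1)[10])
  expect_equal(bc$bbox@anterior - bc$bbox@posterior, gridSpacing(g)[1])
})

test_that("the measured centerline tracks the analytic one at -12 mm offset", {
  g <- defaultGrid()
  rep <- measureCenterlines(renderVolume(phantomSpec(tableHeightOffset = -12), g))
  expect_lt(abs(bodyCenterline(rep) - (-12)), gridSpacing(g)[1] / 2)
})

test_that("scan-range-restricted measurement matches the analytic oracle", {
  g <- defaultGrid()
  sp <- phantomSpec(tableHeightOffset = 10)
  vol <- renderVolume(sp, g)
  rng <- c(30, 150)
  rep <- measureCenterlines(vol, scanRange = rng)
  ana <- analyticCenterlines(sp, scanRange = rng)
  expect_lt(abs(bodyCenterline(rep) - ana$body[["centerline"]]),
            max(gridSpacing(g)) / 2)
  expect_lt(abs(lungCenterline(rep) - ana$lung[["centerline"]]),
            max(gridSpacing(g)) / 2)
  expect_error(bboxAndCenterline(segmentBody(vol), g, c(5000, 6000)),
               "no slices")
})

test_that("truncation detection flags bodies leaving the field of view", {
  g <- tinyGrid()
  contained <- segmentBody(renderVolume(tinySpec(0), g))
  expect_false(detectTruncation(contained, g))
  big <- phantomSpec(bodySemiAxisAP = 150, bodySemiAxisLat = 230,
                     bodyLength = 240, tablePresent = FALSE)
  mask <- segmentBody(renderVolume(big, g))
  expect_true(detectTruncation(mask, g))
  # fraction 0 flags any touch
  one <- contained
  one[1, 30, 3] <- TRUE
  expect_true(detectTruncation(one, g, fraction = 0))
  expect_false(detectTruncation(contained, g, fraction = 0))
})

test_that("centerlines are invariant to affine intensity rescaling", {
  g <- tinyGrid()
  vol <- renderVolume(tinySpec(-9), g)
  scaled <- Volume3D(voxels(vol) * 3 + 0.2, grid3d(vol))
  r1 <- measureCenterlines(vol)
  r2 <- measureCenterlines(scaled)
  expect_equal(bodyCenterline(r1), bodyCenterline(r2))
  expect_equal(lungCenterline(r1), lungCenterline(r2))
})

test_that("shifting the phantom shifts the centerline equivariantly", {
  g <- defaultGrid()
  for (h in c(-18, 11, 27)) {
    r0 <- measureCenterlines(renderVolume(phantomSpec(tableHeightOffset = 0), g))
    rh <- measureCenterlines(renderVolume(phantomSpec(tableHeightOffset = h), g))
    expect_lt(abs((bodyCenterline(rh) - bodyCenterline(r0)) - h),
              gridSpacing(g)[1] / 2)
  }
})

test_that("per-slice centerlines are reported along Z", {
  g <- tinyGrid()
  rep <- measureCenterlines(renderVolume(tinySpec(4), g), perSlice = TRUE)
  psc <- rep@perSliceCenterlines
  expect_length(psc, gridShape(g)[3])
  mid <- psc[!is.na(psc)]
  expect_true(all(abs(mid - 4) <= gridSpacing(g)[1]))
})

test_that("an empty volume yields a 'no body' error", {
  g <- tinyGrid()
  flat <- Volume3D(array(0.5, dim = gridShape(g)), g)
  expect_error(suppressWarnings(segmentBody(flat)), "no body")
})
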