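test_that("population sampling is reproducible and matches its demographics", {
  a <- samplePopulation(3, seed = 7)
  b <- samplePopulation(3, seed = 7)
  expect_identical(lapply(a, bodyDiameterAP), lapply(b, bodyDiameterAP))
  expect_identical(lapply(a, tableHeightOffset), lapply(b, tableHeightOffset))

  big <- samplePopulation(5000, seed = 2)
  dAp <- vapply(big, bodyDiameterAP, 0)
  # truncation at +/- 3 SD barely moves the mean; 3 standard errors around
  # the 243 mm population mean
  expect_lt(abs(mean(dAp) - 243), 3 * 36 / sqrt(5000))
  dLat <- vapply(big, bodyDiameterLat, 0)
  expect_lt(abs(mean(dLat) - 301), 3 * 53 / sqrt(5000))
  expect_gt(cor(dAp, dLat), 0.5)   # diameters are sampled jointly
})

test_that("mis-centering SD solved from the normal CDF yields 60% beyond 10 mm", {
  # P(|X| > 10) = 0.6 for a centred normal => sigma = 10 / qnorm(0.7)
  sigma <- 10 / qnorm(0.7)
  off <- vapply(samplePopulation(5000, miscenterMean = 0, miscenterSD = sigma,
                                 seed = 3),
                tableHeightOffset, 0)
  expect_lt(abs(mean(abs(off) > 10) - 0.60), 0.02)
})

test_that("sampling rejects invalid arguments", {
  expect_error(samplePopulation(0), "positive")
  expect_error(samplePopulation(2, demographics = list(dApSdCm = -1)),
               "non-negative")
})

test_that("phantom validity rejects lungs outside the body", {
  expect_error(phantomSpec(lungCenterOffsets = rbind(c(80, 0, 0), c(0, 0, 0))),
               "contained")
})

test_that("rendered ellipsoid volume matches the analytic value within 1%", {
  sp <- phantomSpec(lungSemiAxes = matrix(numeric(0), 0, 3),
                    lungCenterOffsets = matrix(numeric(0), 0, 3),
                    tablePresent = FALSE)
  vol <- renderVolume(sp, defaultGrid())
  est <- sum(voxels(vol)) / sp@intensityLevels[["soft"]] *
    prod(gridSpacing(vol))
  ana <- 4 / 3 * pi * 121.5 * 150.5 * 150
  expect_lt(abs(est - ana) / ana, 0.01)
})

test_that("a centred phantom has its body centroid on the isocenter", {
  g <- tinyGrid()
  vol <- renderVolume(tinySpec(0, tablePresent = FALSE), g)
  mask <- voxels(vol) >= 0.35
  ys <- axisCoords(g, 1)[which(mask, arr.ind = TRUE)[, 1]]
  expect_lt(abs(mean(ys) - isocenterY(g)), gridSpacing(g)[1] / 2)
})

test_that("body-mask centroid converges as the grid is refined", {
  sp <- tinySpec(-7, tablePresent = FALSE)
  centroidOn <- function(grid) {
    mask <- voxels(renderVolume(sp, grid)) >= 0.35
    mean(axisCoords(grid, 1)[which(mask, arr.ind = TRUE)[, 1]])
  }
  coarse <- centroidOn(Grid3D(c(48L, 48L, 16L), c(8, 8, 18)))
  fine <- centroidOn(Grid3D(c(96L, 96L, 32L), c(4, 4, 9)))
  expect_lt(abs(fine - coarse), 8 / 2)
})

test_that("rendered lungs are contained in the body ellipsoid (voxelized)", {
  g <- tinyGrid()
  sp <- tinySpec(5, tablePresent = FALSE)
  bare <- tinySpec(5, tablePresent = FALSE,
                   lungSemiAxes = matrix(numeric(0), 0, 3),
                   lungCenterOffsets = matrix(numeric(0), 0, 3))
  # every voxel the lungs touch (render difference) lies inside the body
  lungMask <- abs(voxels(renderVolume(sp, g)) -
                    voxels(renderVolume(bare, g))) > 1e-6
  expect_true(any(lungMask))
  idx <- which(lungMask, arr.ind = TRUE)
  yc <- isocenterY(g) + 5
  f <- ((axisCoords(g, 1)[idx[, 1]] - yc) / 100)^2 +
    (axisCoords(g, 2)[idx[, 2]] / 120)^2 +
    (axisCoords(g, 3)[idx[, 3]] / 120)^2
  expect_true(all(f < 1))
})

test_that("a body entirely outside the grid is an error", {
  expect_error(renderVolume(tinySpec(900), tinyGrid()), "outside")
})

test_that("parallel projection reproduces the body shadow width", {
  g <- defaultGrid()
  sp <- phantomSpec(tablePresent = FALSE)
  loc <- projectLocalizer(renderVolume(sp, g), "parallel")
  prof <- colSums(pixels(loc))
  xs <- axisCoords(g, 2)
  supp <- range(xs[prof > 1e-6])
  expect_lt(abs(supp[2] - 150.5), gridSpacing(g)[2])
  expect_lt(abs(supp[1] + 150.5), gridSpacing(g)[2])
})

test_that("divergent projection tends to the parallel one as SDD grows", {
  g <- tinyGrid()
  vol <- renderVolume(tinySpec(10), g)
  par <- projectLocalizer(vol, "parallel")
  div <- projectLocalizer(vol, "divergent", sdd = 1e7)
  expect_lt(max(abs(pixels(par) - pixels(div))), 1e-3)
})

# sub-pixel width of a profile at a given fraction of its maximum
halfMaxWidth <- function(prof, xs, frac = 0.5) {
  thr <- frac * max(prof)
  above <- which(prof > thr)
  i1 <- min(above); i2 <- max(above)
  left <- if (i1 == 1) xs[1] else
    approx(prof[c(i1 - 1, i1)], xs[c(i1 - 1, i1)], thr)$y
  right <- if (i2 == length(prof)) xs[length(xs)] else
    approx(prof[c(i2, i2 + 1)], xs[c(i2, i2 + 1)], thr)$y
  right - left
}

test_that("divergent magnification scales the shadow by m = sdd/(sdd - h)", {
  g <- defaultGrid()
  xs <- axisCoords(g, 2)
  sdd <- 600; h <- 40
  w0 <- halfMaxWidth(colSums(pixels(projectLocalizer(
    renderVolume(phantomSpec(tableHeightOffset = 0, tablePresent = FALSE), g),
    "divergent", sdd = sdd))), xs)
  wh <- halfMaxWidth(colSums(pixels(projectLocalizer(
    renderVolume(phantomSpec(tableHeightOffset = h, tablePresent = FALSE), g),
    "divergent", sdd = sdd))), xs)
  m <- sdd / (sdd - h)
  expect_lt(abs(wh / w0 - m) / m, 0.02)
})

test_that("divergent mode rejects a field of view reaching the source", {
  vol <- renderVolume(tinySpec(), tinyGrid())
  expect_error(projectLocalizer(vol, "divergent", sdd = 100), "source")
})

test_that("analytic centerlines follow the construction", {
  sp <- tinySpec(-12)
  ac <- analyticCenterlines(sp)
  expect_equal(ac$body[["centerline"]], -12)

  # lungs shifted anteriorly by construction: both lungs moved +10 mm
  sp2 <- phantomSpec(tableHeightOffset = 0,
                     lungSemiAxes = rbind(c(40, 30, 60), c(40, 30, 60)),
                     lungCenterOffsets = rbind(c(10, -45, 0), c(10, 45, 0)))
  ac2 <- analyticCenterlines(sp2)
  expect_equal(ac2$lung[["centerline"]] - ac2$body[["centerline"]], 10)

  expect_error(analyticCenterlines(sp, scanRange = c(500, 600)), "disjoint")
})

test_that("scan-range-restricted analytic centerline matches a voxel oracle", {
  g <- defaultGrid()
  sp <- phantomSpec(tableHeightOffset = -9,
                    lungSemiAxes = matrix(numeric(0), 0, 3),
                    lungCenterOffsets = matrix(numeric(0), 0, 3))
  rng <- c(40, 160)    # superior part of the body only
  ac <- analyticCenterlines(sp, scanRange = rng)
  vox <- voxelEllipsoidMid(g, c(-9, 0, 0), c(121.5, 150.5, 150), zRange = rng)
  expect_lt(abs(ac$body[["centerline"]] - vox), gridSpacing(g)[1] / 2)
})

test_that("the rendered intensity grid makes localizers and volumes exact 1e-4 multiples", {
  vol <- renderVolume(tinySpec(3), tinyGrid())
  expect_equal(voxels(vol), round(voxels(vol) * 1e4) * 1e-4)
})

test_that("the divergent localizer carries enough signal to decode table height", {
  # linear (ridge) readout of the preprocessed localizer recovers the
  # table-height offset on held-out phantoms: the information the network
  # is expected to exploit is present in its input
  g <- defaultGrid()
  n <- 250
  specs <- samplePopulation(n, seed = 606)
  X <- matrix(0, n, 48 * 32)
  off <- vapply(specs, tableHeightOffset, 0)
  for (i in seq_along(specs)) {
    vol <- renderVolume(specs[[i]], g)
    loc <- projectLocalizer(vol, "divergent", sdd = 600)
    X[i, ] <- as.numeric(resizeLocalizer(normalize01(loc), c(48L, 32L)))
  }
  tr <- 1:200; te <- 201:n
  Xc <- scale(X[tr, ], scale = FALSE)
  beta <- solve(crossprod(Xc) + 1e-4 * diag(ncol(X)),
                crossprod(Xc, off[tr] - mean(off[tr])))
  pred <- scale(X[te, ], center = attr(Xc, "scaled:center"),
                scale = FALSE) %*% beta + mean(off[tr])
  expect_gt(cor(pred, off[te]), 0.9)
})
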