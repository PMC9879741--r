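test_that("crop is a no-op when localizer and volume share their extent", {
  cs <- renderCase(tinySpec(3), tinyGrid())
  cr <- cropToCommonExtent(cs$localizer, cs$volume)
  expect_identical(voxels(cr$volume), voxels(cs$volume))
  expect_identical(pixels(cr$localizer), pixels(cs$localizer))
  expect_equal(rbind(cr$cropRecord$ap, cr$cropRecord$lat, cr$cropRecord$z),
               unname(gridExtent(grid3d(cs$volume))))
})

test_that("crop restricts both images to the physical intersection", {
  g <- Grid3D(c(32L, 32L, 26L), c(8, 8, 12), origin = c(-124, -124, 6))
  # volume z in [0, 312); localizer shifted superiorly by 60 mm
  vol <- Volume3D(array(runif(32 * 32 * 26), c(32, 32, 26)), g)
  loc <- Localizer2D(matrix(runif(26 * 32), 26, 32),
                     pixelSpacing = c(12, 8), position = c(66, -124))
  cr <- cropToCommonExtent(loc, vol)
  zExt <- gridExtent(grid3d(cr$volume))[3, ]
  expect_gte(zExt[1], 60 - 12)          # within one voxel of the overlap
  expect_lte(zExt[2], 312 + 12)
  expect_equal(unname(localizerExtent(cr$localizer)[1, 1]), unname(zExt[1]),
               tolerance = 12)
  # voxel payload is the matching subarray
  expect_identical(voxels(cr$volume), voxels(vol)[, , 6:26])
})

test_that("disjoint extents are an error", {
  cs <- renderCase(tinySpec(), tinyGrid())
  far <- Localizer2D(pixels(cs$localizer), cs$localizer@pixelSpacing,
                     position = c(5000, 5000))
  expect_error(cropToCommonExtent(far, cs$volume), "overlap")
})

test_that("normalize01 is affine, idempotent and warns on constant input", {
  expect_equal(normalize01(c(0, 5, 10)), c(0, 0.5, 1))
  x <- matrix(runif(20), 4, 5)
  n1 <- normalize01(x)
  expect_equal(normalize01(n1), n1)
  expect_warning(z <- normalize01(matrix(3, 2, 2)), "constant")
  expect_true(all(z == 0))
})

test_that("resize honours the full-scale shape contract", {
  cs <- renderCase(tinySpec(), tinyGrid())
  li <- resizeLocalizer(normalize01(cs$localizer))
  expect_identical(dim(li), c(144L, 64L))
  vo <- resizeVolumeCoronal(normalize01(cs$volume))
  expect_identical(dim(vo), c(184L, 144L, 64L))
  expect_true(min(li) >= 0 && max(li) <= 1 && min(vo) >= 0 && max(vo) <= 1)
  expect_identical(attr(vo, "orientation"), "coronal")
})

test_that("resizing a constant image stays constant and ramps keep endpoints", {
  const <- matrix(0.4, 30, 20)
  out <- resizeLocalizer(const, c(12L, 10L))
  expect_equal(out, matrix(0.4, 12, 10))
  # linear ramp along the lateral axis: resampled values must lie on the ramp
  ramp <- matrix(rep(seq(0, 1, length.out = 40), each = 20), 20, 40)
  out2 <- resizeLocalizer(ramp, c(20L, 20L))      # input is (z, lat)
  expected <- (seq_len(20) - 0.5) * 40 / 20 + 0.5
  expected <- (pmin(pmax(expected, 1), 40) - 1) / 39
  expect_equal(out2[, 1], expected, tolerance = 1e-6)
})

test_that("axial/coronal reorientation is a lossless permutation", {
  v <- array(runif(6 * 5 * 4), c(6, 5, 4))
  coronal <- aperm(v, c(2, 3, 1))       # AP becomes the slice axis
  expect_identical(aperm(coronal, c(3, 1, 2)), v)
  # resizing to the same shape is the identity up to interpolation exactness
  expect_equal(as.numeric(resizeVolumeCoronal(v, dim(v))), as.numeric(v))
})

test_that("cohort split is stratified, disjoint, exhaustive and seeded", {
  s <- splitCohort(rep("C1", 10), seed = 1)
  expect_length(s$train, 8)
  expect_length(s$test, 2)
  expect_identical(sort(c(s$train, s$test)), 1:10)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(splitCohort(rep("C1", 10), seed = 1), s)

  src <- rep(c("C1", "C2"), c(10, 5))
  s2 <- splitCohort(src, seed = 4)
  expect_identical(sum(src[s2$train] == "C1"), 8L)
  expect_identical(sum(src[s2$train] == "C2"), 4L)

  expect_error(splitCohort(rep("C1", 10), fraction = 1.2), "fraction")
  expect_error(splitCohort("C1"), "two cases")
})

test_that("mm coordinates survive crop -> resize -> inverse mapping", {
  cs <- renderCase(tinySpec(5), tinyGrid())
  cr <- cropToCommonExtent(cs$localizer, cs$volume)
  outShape <- c(32L, 24L, 12L)
  pg <- predictionGrid(cr$cropRecord, outShape)
  for (p in list(c(-40, 10, 30), c(12, -60, -100))) {
    idx <- vapply(1:3, function(ax)
      which.min(abs(axisCoords(pg, ax) - p[ax])), 0L)
    back <- vapply(1:3, function(ax) axisCoords(pg, ax)[idx[ax]], 0)
    expect_true(all(abs(back - p) <= gridSpacing(pg) / 2))
  }
  expect_equal(isocenterY(pg), isocenterY(grid3d(cs$volume)))
})

test_that("training pairs satisfy their invariants across a simulated cohort", {
  g <- tinyGrid()
  specs <- samplePopulation(15, seed = 21)
  for (sp in specs) {
    vol <- renderVolume(sp, g)
    loc <- projectLocalizer(vol, "divergent")
    tp <- makeTrainingPair(loc, vol, locShape = c(24L, 16L),
                           volShape = c(32L, 24L, 16L))
    expect_identical(dim(localizerIn(tp)), c(24L, 16L))
    expect_identical(dim(volumeOut(tp)), c(32L, 24L, 16L))
    rng <- range(localizerIn(tp), volumeOut(tp))
    expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  }
})
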