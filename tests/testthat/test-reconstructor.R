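test_that("bottleneck spatial size shrinks by 2^depth with the padding rule", {
  cfg <- modelConfig(depth = 5L, inputShape = c(144L, 64L))
  # 144 is not divisible by 32 -> padded to 160
  expect_identical(bottleneckShape(cfg), c(5L, 2L))
  cfg3 <- modelConfig(depth = 3L, inputShape = c(48L, 32L))
  expect_identical(bottleneckShape(cfg3), c(6L, 4L))
})

test_that("parameter count of a depth-1 model matches the layer formula", {
  c0 <- 6L; bins <- 10L
  cfg <- modelConfig(depth = 1L, baseChannels = c0, outputApBins = bins,
                     inputShape = c(16L, 16L))
  m <- buildModel(cfg, seed = 1)
  convP <- function(ci, co, bn) 9 * ci * co + co + if (bn) 2 * co else 0
  # input is image + 2 coordinate channels; the level-1 skip carries all 3;
  # the head sees the decoder output plus the pooled bottleneck broadcast
  expected <- (convP(3, c0, TRUE) + convP(c0, c0, TRUE)) +       # encoder
    (convP(c0 + 3, c0, TRUE) + convP(c0, c0, TRUE)) +            # decoder
    convP(2 * c0, bins, FALSE)                                   # output head
  expect_identical(countParams(m), as.integer(expected))
})

test_that("model building is deterministic under a fixed seed", {
  cfg <- modelConfig(depth = 2L, baseChannels = 4L, outputApBins = 8L,
                     inputShape = c(16L, 16L))
  expect_identical(buildModel(cfg, seed = 5)$params,
                   buildModel(cfg, seed = 5)$params)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- modelConfig(depth = 2L, baseChannels = 3L, outputApBins = 5L,
                     inputShape = c(8L, 8L))
  m <- buildModel(cfg, seed = 3)
  set.seed(9)
  x <- matrix(runif(64), 8, 8)
  tgt <- array(runif(8 * 8 * 5), c(8, 8, 5))
  lossOf <- function(mm) {
    fw <- ctcenterline:::forwardNet(mm, x)
    mean((fw$out - tgt)^2)
  }
  fw <- ctcenterline:::forwardNet(m, x)
  gr <- ctcenterline:::backwardNet(m, fw, 2 * (fw$out - tgt) / length(tgt))
  flat <- function(l, pre = "") {
    out <- list()
    for (n in names(l)) {
      v <- l[[n]]
      if (is.list(v)) out <- c(out, flat(v, paste0(pre, n, ".")))
      else out[[paste0(pre, n)]] <- v
    }
    out
  }
  setp <- function(l, path, ii, delta) {
    if (length(path) == 1) { l[[path]][ii] <- l[[path]][ii] + delta; l }
    else { l[[path[1]]] <- setp(l[[path[1]]], path[-1], ii, delta); l }
  }
  gf <- flat(gr)
  eps <- 1e-5
  worst <- 0
  set.seed(5)
  for (nm in names(gf)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    g <- gf[[nm]]
    for (ii in sample(length(g), min(3, length(g)))) {
      m2 <- m; m2$params <- setp(m2$params, path, ii, eps)
      m3 <- m; m3$params <- setp(m3$params, path, ii, -eps)
      num <- (lossOf(m2) - lossOf(m3)) / (2 * eps)
      worst <- max(worst, abs(num - g[ii]) / max(1e-6, abs(num) + abs(g[ii])))
    }
  }
  expect_lt(worst, 1e-3)   # slack for occasional ReLU kinks
})

test_that("zero epochs leave the model untouched with an empty history", {
  cs <- renderCase(tinySpec(), tinyGrid())
  tp <- makeTrainingPair(cs$localizer, cs$volume, c(24L, 16L), c(32L, 24L, 16L))
  cfg <- modelConfig(depth = 2L, baseChannels = 4L, outputApBins = 32L,
                     inputShape = c(24L, 16L))
  m <- buildModel(cfg, seed = 2)
  fit <- trainModel(m, list(tp), trainConfig(epochs = 0L))
  expect_identical(fit$model$params, m$params)
  expect_length(fit$history, 0)
})

test_that("training is reproducible and shapes are checked", {
  cs <- renderCase(tinySpec(4), tinyGrid())
  tp <- makeTrainingPair(cs$localizer, cs$volume, c(24L, 16L), c(32L, 24L, 16L))
  cfg <- modelConfig(depth = 2L, baseChannels = 4L, outputApBins = 32L,
                     inputShape = c(24L, 16L))
  m <- buildModel(cfg, seed = 2)
  f1 <- trainModel(m, list(tp), trainConfig(epochs = 3L, seed = 9))
  f2 <- trainModel(m, list(tp), trainConfig(epochs = 3L, seed = 9))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)

  wrong <- makeTrainingPair(cs$localizer, cs$volume, c(16L, 16L),
                            c(32L, 16L, 16L))
  expect_error(trainModel(m, list(wrong)), "shapes")
})

test_that("a single pair can be overfit and its bounding box recovered", {
  g <- defaultGrid()
  vol <- renderVolume(phantomSpec(tableHeightOffset = -10), g)
  loc <- projectLocalizer(vol, "divergent")
  tp <- makeTrainingPair(loc, vol, c(24L, 16L), c(32L, 24L, 16L))
  cfg <- modelConfig(depth = 2L, baseChannels = 24L, outputApBins = 32L,
                     inputShape = c(24L, 16L))
  m <- buildModel(cfg, seed = 1)
  fit <- trainModel(m, list(tp), trainConfig(epochs = 800L, lr = 2e-2,
                                             seed = 2))
  final <- tail(fit$history, 1)
  expect_lt(final, 1e-3)
  expect_lt(final, fit$history[1] / 100)

  pv <- predictVolume(fit$model, tp)
  gtRep <- measureCenterlines(vol)
  dlRep <- measureCenterlines(pv, source = "predicted")
  # bounding-box limits within one coarse voxel of the ground truth
  sp <- max(gridSpacing(pv))
  expect_lt(abs(bodyBBox(dlRep)@anterior - bodyBBox(gtRep)@anterior), sp)
  expect_lt(abs(bodyBBox(dlRep)@posterior - bodyBBox(gtRep)@posterior), sp)
})

test_that("checkpoints restore bit-identical predictions", {
  cs <- renderCase(tinySpec(3), tinyGrid())
  tp <- makeTrainingPair(cs$localizer, cs$volume, c(24L, 16L), c(32L, 24L, 16L))
  cfg <- modelConfig(depth = 2L, baseChannels = 4L, outputApBins = 32L,
                     inputShape = c(24L, 16L))
  fit <- trainModel(buildModel(cfg, seed = 4), list(tp),
                    trainConfig(epochs = 2L, seed = 5))
  f <- file.path(tempdir(), "model.ckpt")
  saveModel(fit$model, f)
  m2 <- loadModel(f)
  expect_identical(voxels(predictVolume(fit$model, tp)),
                   voxels(predictVolume(m2, tp)))
  file.remove(f)
})

test_that("prediction rejects inputs preprocessed with another shape", {
  cfg <- modelConfig(depth = 2L, baseChannels = 4L, outputApBins = 32L,
                     inputShape = c(24L, 16L))
  m <- buildModel(cfg, seed = 1)
  cs <- renderCase(tinySpec(), tinyGrid())
  tp <- makeTrainingPair(cs$localizer, cs$volume, c(16L, 16L), c(32L, 16L, 16L))
  expect_error(predictVolume(m, tp), "shape")
})
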