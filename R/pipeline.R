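## End-to-end experiment orchestration: simulate -> preprocess -> train ->
## predict -> measure -> evaluate, reproducible under a single seed. Stages
## abort with the stage name and case id on failure; per-case volumes are
## streamed (rendered, projected, measured, then released) so cohort size is
## not memory-bound, unless persist = "all" asks for every artifact on disk.

#' Default experiment configuration
#'
#' Desk-scale defaults: 250 phantoms on the \code{\link{defaultGrid}} (4 mm
#' vertical pitch), divergent localizers at SDD 600 mm, 48 x 32 localizer /
#' 64 x 48 x 32 coronal matrices, a depth-3 network trained 20 epochs.
#' Full-scale matrices (144 x 64 / 184 x 144 x 64, depth 5, 50 epochs) are
#' reached by overriding \code{preprocess}, \code{model} and \code{train}.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param outDir output directory (\code{NULL} = in-memory only).
#' @param n cohort size.
#' @return Nested config list (class \code{RunConfig}).
#' @export
defaultRunConfig <- function(seed = 1L, outDir = NULL, n = 250L) {
  structure(list(
    seed = as.integer(seed),
    outDir = outDir,
    persist = "reports",
    phantom = list(n = as.integer(n), demographics = list(),
                   miscenterMean = 9.35, miscenterSD = 14.94,
                   blanketProb = 0, sourceId = "C1",
                   gridShape = c(96L, 96L, 64L), gridSpacing = c(4, 4, 6)),
    projection = list(mode = "divergent", sdd = 600),
    preprocess = list(locShape = c(48L, 32L), volShape = c(64L, 48L, 32L)),
    split = list(fraction = 0.8, excludeTruncated = TRUE),
    model = list(depth = 3L, baseChannels = 16L),
    train = list(epochs = 20L, lr = 3e-3, loss = "mse"),
    centerline = list(bodyThreshold = 0.25, lungThreshold = 0.45)
  ), class = "RunConfig")
}

validateRunConfig <- function(config) {
  need <- c("seed", "phantom", "projection", "preprocess", "split", "model",
            "train", "centerline")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("invalid run config, missing block(s): ",
         paste(missing, collapse = ", "))
  if (config$phantom$n < 5) stop("phantom$n too small for a split experiment")
  if (!identical(config$preprocess$volShape[2:3],
                 as.integer(config$preprocess$locShape)))
    stop("volShape lateral/Z must match locShape (shared network plane)")
  invisible(config)
}

stageTry <- function(stage, case, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for case %s: %s",
                 stage, case, conditionMessage(e)), call. = FALSE))
}

#' Simulate a cohort to disk
#'
#' Renders each sampled phantom, projects its localizer and writes, per
#' case, the volume (NIfTI by default, a DICOM axial series with
#' \code{dicom = TRUE}), the localizer (DICOM scout), and one row in a
#' ground-truth CSV (spec fields plus analytic body/lung centerlines).
#'
#' @param n cohort size.
#' @param outDir output directory.
#' @param seed integer.
#' @param grid a \code{\link{Grid3D-class}}.
#' @param mode,sdd projection geometry (see \code{\link{projectLocalizer}}).
#' @param dicom write the volume as a DICOM series instead of NIfTI.
#' @param ... forwarded to \code{\link{samplePopulation}}.
#' @return Invisibly, the ground-truth data.frame.
#' @export
simulateCohort <- function(n, outDir, seed = 1L, grid = defaultGrid(),
                           mode = "divergent", sdd = 600, dicom = FALSE,
                           ...) {
  specs <- samplePopulation(n, seed = seed, ...)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    id <- caseId(sp)
    vol <- stageTry("render", id, renderVolume(sp, grid))
    loc <- stageTry("project", id,
                    projectLocalizer(vol, mode = mode, sdd = sdd,
                                     sourceId = sub("-.*$", "", id)))
    gt <- analyticCenterlines(sp, isocenterY = grid@isocenterY)
    caseDir <- file.path(outDir, id)
    dir.create(caseDir, showWarnings = FALSE)
    if (dicom) {
      writeDicomSeries(vol, file.path(caseDir, "axial"), seriesId = i)
    } else {
      writeVolumeNifti(vol, file.path(caseDir, "volume.nii"))
    }
    writeDicomScout(loc, file.path(caseDir, "localizer.dcm"), seriesId = i)
    rows[[i]] <- data.frame(
      caseId = id, dAp = bodyDiameterAP(sp), dLat = bodyDiameterLat(sp),
      bodyLength = sp@bodyLength, tableHeightOffset = tableHeightOffset(sp),
      blanket = sp@blanketPresent,
      bodyCenterline = gt$body[["centerline"]],
      lungCenterline = gt$lung[["centerline"]])
  }
  gtDf <- do.call(rbind, rows)
  write.csv(gtDf, file.path(outDir, "ground_truth.csv"), row.names = FALSE)
  invisible(gtDf)
}

#' Run a full simulated positioning experiment
#'
#' simulate -> preprocess -> split -> train -> predict -> measure ->
#' evaluate under one master seed. Ground-truth centerlines are measured on
#' the rendered volumes with the same centerline module applied to the
#' predictions, exactly as in the clinical protocol.
#'
#' @param config a \code{\link{defaultRunConfig}}-style list.
#' @return List: \code{errors} (per-test-case positioning errors),
#'   \code{summary} (\code{\link{cohortSummary}}), \code{stats}
#'   (Mann-Whitney BCAP vs BCMP on signed and absolute errors, Spearman
#'   |BCAP| vs body size, KS normality of BCAP), \code{history} (training
#'   loss), \code{flags} (truncation/lung-fallback counts), \code{model},
#'   and \code{config}.
#' @export
runExperiment <- function(config = defaultRunConfig()) {
  validateRunConfig(config)
  seed <- config$seed
  ph <- config$phantom
  grid <- Grid3D(ph$gridShape, ph$gridSpacing)
  specs <- samplePopulation(ph$n, demographics = ph$demographics,
                            miscenterMean = ph$miscenterMean,
                            miscenterSD = ph$miscenterSD,
                            blanketProb = ph$blanketProb,
                            seed = seed, sourceId = ph$sourceId)
  persistAll <- !is.null(config$outDir) && identical(config$persist, "all")
  if (persistAll) {
    dir.create(file.path(config$outDir, "cohort"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(config$outDir, "predictions"), showWarnings = FALSE)
  }

  n <- ph$n
  pairs <- vector("list", n)
  gtReports <- vector("list", n)
  flags <- list(truncated = 0L, lungFallback = 0L)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    id <- caseId(sp)
    vol <- stageTry("simulate", id, renderVolume(sp, grid))
    loc <- stageTry("simulate", id,
                    projectLocalizer(vol, mode = config$projection$mode,
                                     sdd = config$projection$sdd,
                                     sourceId = ph$sourceId))
    pairs[[i]] <- stageTry("preprocess", id,
                           makeTrainingPair(loc, vol,
                                            locShape = config$preprocess$locShape,
                                            volShape = config$preprocess$volShape))
    gtReports[[i]] <- stageTry("measure", id,
      measureCenterlines(vol,
                         bodyThreshold = config$centerline$bodyThreshold,
                         lungThreshold = config$centerline$lungThreshold,
                         source = "ground_truth", caseId = id))
    flags$truncated <- flags$truncated + isTruncated(gtReports[[i]])
    flags$lungFallback <- flags$lungFallback + gtReports[[i]]@lungFallback
    if (persistAll) {
      caseDir <- file.path(config$outDir, "cohort", id)
      dir.create(caseDir, showWarnings = FALSE)
      writeVolumeNifti(vol, file.path(caseDir, "volume.nii"))
      writeDicomScout(loc, file.path(caseDir, "localizer.dcm"), seriesId = i)
    }
  }

  ## truncated bodies make the anterior/posterior limits unmeasurable; the
  ## clinical protocol excludes such cases, and so does the automatic flag
  keep <- seq_len(n)
  if (isTRUE(config$split$excludeTruncated))
    keep <- which(!vapply(gtReports, isTruncated, TRUE))
  if (length(keep) < 5) stop("too few untruncated cases to run an experiment")
  flags$excluded <- n - length(keep)
  split <- splitCohort(rep(ph$sourceId, length(keep)),
                       fraction = config$split$fraction, seed = seed + 1L)
  split$train <- keep[split$train]
  split$test <- keep[split$test]
  mc <- modelConfig(depth = config$model$depth,
                    baseChannels = config$model$baseChannels,
                    outputApBins = config$preprocess$volShape[1],
                    inputShape = config$preprocess$locShape)
  model <- buildModel(mc, seed = seed + 2L)
  tc <- trainConfig(epochs = config$train$epochs, lr = config$train$lr,
                    loss = config$train$loss, seed = seed + 3L)
  fit <- stageTry("train", "(cohort)", trainModel(model, pairs[split$train], tc))
  model <- fit$model
  if (persistAll)
    saveModel(model, file.path(config$outDir, "model.ckpt"))

  rows <- vector("list", length(split$test))
  for (j in seq_along(split$test)) {
    i <- split$test[j]
    id <- caseId(specs[[i]])
    predVol <- stageTry("predict", id, predictVolume(model, pairs[[i]]))
    predReport <- stageTry("measure", id,
      measureCenterlines(predVol,
                         bodyThreshold = config$centerline$bodyThreshold,
                         lungThreshold = config$centerline$lungThreshold,
                         source = "predicted", caseId = id))
    rows[[j]] <- positioningErrors(gtReports[[i]], predReport,
                                   bodySize = effectiveDiameter(specs[[i]]))
    if (persistAll)
      writeVolumeNifti(predVol,
                       file.path(config$outDir, "predictions",
                                 paste0(id, ".nii")))
  }
  errors <- do.call(rbind, rows)
  summary <- cohortSummary(errors)
  stats <- list(
    mwSigned = mannWhitney(errors$bcap, errors$bcmp),
    mwAbsolute = mannWhitney(errors$absBcap, errors$absBcmp),
    spearmanSize = spearmanCorr(errors$bodySize, errors$absBcap),
    ksBcap = if (nrow(errors) >= 5) ksNormality(errors$bcap, seed = seed + 4L)
             else list(statistic = NA_real_, p = NA_real_))
  result <- list(errors = errors, summary = summary, stats = stats,
                 history = fit$history, flags = flags, model = model,
                 config = config)
  if (!is.null(config$outDir)) {
    repDir <- file.path(config$outDir, "reports")
    dir.create(repDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(errors, file.path(repDir, "errors.csv"), row.names = FALSE)
    write.csv(summary, file.path(repDir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(stats, file.path(repDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(package = "ctcenterline",
                     version = as.character(utils::packageVersion("ctcenterline")),
                     seed = seed,
                     stageSeeds = list(population = seed, split = seed + 1L,
                                       weights = seed + 2L, train = seed + 3L,
                                       ks = seed + 4L),
                     flags = flags,
                     config = unclass(config))
    yaml::write_yaml(manifest, file.path(repDir, "manifest.yaml"))
  }
  result
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing blocks take the defaults of
#' \code{\link{defaultRunConfig}}.
#'
#' @param path YAML file.
#' @return A \code{RunConfig} list.
#' @export
readRunConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  unknown <- setdiff(names(usr), names(base))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(unclass(base), usr)
  for (blk in c("phantom", "preprocess", "model", "train"))
    for (f in intersect(names(cfg[[blk]]),
                        c("n", "gridShape", "locShape", "volShape", "depth",
                          "baseChannels", "epochs")))
      cfg[[blk]][[f]] <- as.integer(cfg[[blk]][[f]])
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "RunConfig")
}
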