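test_that("detail tasks enqueued by an overview callback are imaged before the next overview", {
  p <- oddoPipeline(seed = 3, nOverviews = 2)
  log <- runLoop(p$queue, p$levels, p$microscope, store = p$store)
  acq <- logAcquisitions(log)
  expect_equal(acq$level,
               c("overview", "detail", "detail",
                 "overview", "detail", "detail"))
  expect_equal(log$stopReason, "queue-empty")
  ## persist-before-callbacks: detail parents are the triggering overviews
  expect_equal(storeCount(p$store), 6L)
})

test_that("an empty queue halts the loop with reason queue-empty", {
  p <- oddoPipeline(seed = 3, nOverviews = 1)
  log <- runLoop(p$queue, p$levels, p$microscope)
  expect_equal(log$stopReason, "queue-empty")
})

test_that("max_images stops after exactly n persisted measurements", {
  p <- oddoPipeline(seed = 3, nOverviews = 50)
  log <- runLoop(p$queue, p$levels, p$microscope, store = p$store,
                 stops = makeStoppingCriterion("max_images", n = 1))
  expect_equal(log$imagesAcquired, 1L)
  expect_equal(storeCount(p$store), 1L)
  expect_match(log$stopReason, "max-images")
})

test_that("max_time stops by simulated clock arithmetic", {
  ## 40 s per acquisition, 100 s budget -> exactly 3 measurements
  scene <- generateScene(1, density = 0, extent = c(50, 50))
  ms <- simulatedMicroscope(scene, clock = clockModel(
    perLine = 0, perFrame = 0, perMeasurement = 40, stageMovePerUm = 0))
  small <- taskTree(25, 25, 1, range = c(5, 5, 1), pixel = c(1, 1, 1))
  refill <- function(state) list(acquisitionTask("overview", small))
  levels <- list(hierarchyLevel("detail", 1L),
                 hierarchyLevel("overview", 2L, callbacks = list(refill)))
  q <- taskQueue(levels)
  enqueueTask(q, acquisitionTask("overview", small), clock = 0)
  log <- runLoop(q, levels, ms,
                 stops = makeStoppingCriterion("max_time", t = 100))
  expect_equal(log$imagesAcquired, 3L)
})

test_that("invalid stopping criteria are rejected at construction", {
  expect_error(makeStoppingCriterion("max_images", n = 0), "n >= 1")
  expect_error(makeStoppingCriterion("max_time", t = 0), "t > 0")
})

test_that("a failing callback is logged and later callbacks still run", {
  p <- oddoPipeline(seed = 3, nOverviews = 1)
  boom <- function(state) stop("detector exploded")
  extra <- new.env(); extra$ran <- FALSE
  after <- function(state) { extra$ran <- TRUE; NULL }
  p$levels[[2]]@callbacks <- c(list(boom), p$levels[[2]]@callbacks,
                               list(after))
  q <- taskQueue(p$levels)
  small <- taskTree(25, 25, 1, range = c(8, 8, 1), pixel = c(1, 1, 1))
  enqueueTask(q, acquisitionTask("overview", small), clock = 0)
  log <- runLoop(q, p$levels, p$microscope)
  expect_true(extra$ran)
  events <- vapply(log$records, function(r) r$event, character(1))
  expect_true("callback-failed" %in% events)
  expect_equal(log$stopReason, "queue-empty")
})

test_that("the loop advances the clock to the earliest eligible delayed task", {
  scene <- generateScene(1, density = 0, extent = c(50, 50))
  ms <- simulatedMicroscope(scene)
  levels <- twoLevels()
  q <- taskQueue(levels)
  small <- taskTree(25, 25, 1, range = c(5, 5, 1), pixel = c(1, 1, 1))
  enqueueTask(q, acquisitionTask("overview", small, delay = 120), clock = 0)
  log <- runLoop(q, levels, ms)
  acq <- logAcquisitions(log)
  expect_gte(acq$clock[1], 120)
  expect_equal(log$imagesAcquired, 1L)
})

test_that("no-detection stopping fires on a blank scene", {
  scene <- generateScene(5, density = 0, extent = c(200, 200))
  ms <- simulatedMicroscope(scene)
  registry <- roiRegistry()
  small <- list(mode = "confocal", channels = 1, power = 30, dwell = 1e-5,
                scan = list(range = list(x = 50, y = 50, z = 2),
                            pixel = list(x = 1, y = 1, z = 1)))
  pos <- positionBlock("grid", origin = c(25, 25, 1), pitch = 50,
                       rows = 4, cols = 4)
  pos(NULL)
  detailGen <- acquisitionTaskGenerator(
    "detail",
    blocks = list(settings = settingsBlock(list(
                    scan = list(pixel = list(x = 0.5, y = 0.5, z = 1)))),
                  stage = stagePositionBlock(),
                  det = detectionBlock(
                    nucleusDetector(intensityThreshold = 60, minPixels = 20),
                    registry = registry, minFov = 2)))
  nextOv <- acquisitionTaskGenerator(
    "overview", blocks = list(settings = settingsBlock(small),
                              position = pos))
  levels <- list(hierarchyLevel("detail", 1L),
                 hierarchyLevel("overview", 2L,
                                callbacks = list(detailGen, nextOv)))
  q <- taskQueue(levels)
  enqueueTask(q, acquisitionTask("overview", deepMerge(
    small, list(stage = list(x = 25, y = 25, z = 1)))), clock = 0)
  log <- runLoop(q, levels, ms, registry = registry,
                 stops = stopWhenNothingFound(5, "overview"))
  expect_match(log$stopReason, "no-objects")
  expect_equal(log$imagesAcquired, 5L)
})

test_that("identical seed and configuration give byte-identical logs and stores", {
  runOnce <- function(dir) {
    p <- oddoPipeline(seed = 9, nOverviews = 2, storeRoot = dir)
    logPath <- file.path(dir, "log.jsonl")
    runLoop(p$queue, p$levels, p$microscope, store = p$store,
            logPath = logPath)
    files <- sort(list.files(dir, recursive = TRUE))
    list(files = files,
         hashes = vapply(file.path(dir, files), function(f) {
           paste(as.character(readBin(f, "raw", file.size(f))),
                 collapse = "")
         }, character(1), USE.NAMES = FALSE))
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- runOnce(d1)
  r2 <- runOnce(d2)
  expect_identical(r1$files, r2$files)
  expect_identical(r1$hashes, r2$hashes)
})
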