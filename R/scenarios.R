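## End-to-end study scenarios -----------------------------------------------------
##
## Self-contained pipeline runs at desk scale: each function builds its scene,
## pipeline and stopping criteria with fixed study conditions and returns the
## measured quantities. They double as worked examples and as the basis of the
## reproducibility script.

.serpentine <- function(origin, pitch, rows, cols) {
  out <- list()
  for (r in seq_len(rows) - 1L) {
    cs <- seq_len(cols) - 1L
    if (r %% 2L == 1L) cs <- rev(cs)
    for (cc in cs) {
      out[[length(out) + 1L]] <- c(origin[1] + cc * pitch,
                                   origin[2] + r * pitch)
    }
  }
  out
}

#' Demo: hierarchical overview-detail FISH imaging
#'
#' A two-level pipeline on a seeded virtual scene of nuclei carrying
#' colocalizing two-channel spot pairs: confocal overviews walk a spiral;
#' after each overview, colocalizing spot pairs are detected and small STED
#' detail stacks are enqueued at higher priority around them, with ROI-registry
#' deduplication.
#'
#' @param seed integer seed
#' @param maxImages stop after this many measurements
#' @param density nuclei per field-of-view area
#' @return list: the experiment \code{log}, per-level \code{counts}, the
#'   \code{store}, \code{registry} and \code{scene}
#' @export
runHierarchicalDemo <- function(seed, maxImages = 12, density = 1.5) {
  scene <- generateScene(seed, density = density, extent = c(160, 160),
                         pairSpots = 2, surfaceSpots = 0,
                         spotBrightness = 150, bodyBrightness = 100)
  microscope <- simulatedMicroscope(scene)
  store <- measurementStore()
  registry <- roiRegistry()

  overviewSettings <- list(
    mode = "confocal", channels = c(1, 2, 3), power = 30, dwell = 1e-5,
    scan = list(range = list(x = 50, y = 50, z = 6),
                pixel = list(x = 0.15, y = 0.15, z = 0.5)))
  detailSettings <- list(
    mode = "sted2d", channels = c(2, 3), power = 30, dwell = 1e-5,
    scan = list(range = list(x = 2, y = 2, z = 2),
                pixel = list(x = 0.05, y = 0.05, z = 0.5)))

  detailGen <- acquisitionTaskGenerator(
    "detail",
    blocks = list(
      settings = settingsBlock(detailSettings),
      stage = stagePositionBlock(),
      rois = detectionBlock(colocDetector(channels = c(2, 3), boxSize = 2,
                                          peakThreshold = 8),
                            registry = registry, minFov = 2)),
    name = "detail-from-coloc")
  ## spiral walker; the first spiral position is taken by the initial task
  spiral <- positionBlock("spiral", origin = c(80, 80, 3), pitch = 45)
  spiral(NULL)
  nextOverview <- acquisitionTaskGenerator(
    "overview",
    blocks = list(settings = settingsBlock(overviewSettings),
                  position = spiral),
    name = "next-overview")

  levels <- list(
    hierarchyLevel("detail", 1L),
    hierarchyLevel("overview", 2L, callbacks = list(detailGen, nextOverview)))
  queue <- taskQueue(levels)
  enqueueTask(queue, acquisitionTask("overview", deepMerge(
    overviewSettings, list(stage = list(x = 80, y = 80, z = 3)))), clock = 0)

  log <- runLoop(queue, levels, microscope,
                 stops = makeStoppingCriterion("max_images", n = maxImages),
                 store = store, registry = registry)
  acq <- logAcquisitions(log)
  list(log = log, acquisitions = acq, counts = table(acq$level),
       store = store, registry = registry, scene = scene)
}

#' Focus-map demo: software autofocus on a tilted slide
#'
#' Runs a single-level overview pipeline over a serpentine rows x cols stage
#' grid on a scene whose slide surface is the plane z = a x + b y + c. The
#' next-overview generator carries an image-based focus-update block, so the
#' applied stage z tracks the tilted sample; regressing the applied focus
#' position on stage (x, y) recovers the tilt coefficients.
#'
#' @param seed integer seed
#' @param rows,cols grid dimensions
#' @param pitch grid pitch (um)
#' @param tilt tilt coefficients (a, b, c)
#' @param density nuclei per field-of-view area
#' @return list: \code{focusMap} (stage x, y, applied z per overview),
#'   \code{fit} (recovered a, b), \code{relErr} (relative errors vs truth)
#' @export
runFocusMapDemo <- function(seed, rows = 10, cols = 10, pitch = 50,
                            tilt = c(0.004, -0.006, 1), density = 4) {
  origin <- c(25, 25)
  extent <- c(origin[1] * 2 + pitch * (cols - 1),
              origin[2] * 2 + pitch * (rows - 1))
  scene <- generateScene(seed, density = density, extent = extent,
                         semiAxesZ = c(2.3, 2.5), tilt = tilt,
                         bodyBrightness = 120)
  microscope <- simulatedMicroscope(scene)

  overviewSettings <- list(
    mode = "confocal", channels = 1, power = 30, dwell = 1e-5,
    scan = list(range = list(x = 50, y = 50, z = 4),
                pixel = list(x = 0.8, y = 0.8, z = 0.4)))
  positions <- .serpentine(origin, pitch, rows, cols)
  posBlock <- positionBlock("list", positions = positions)
  posBlock(NULL)  # first grid position is the seeded initial task
  nextOverview <- acquisitionTaskGenerator(
    "overview",
    blocks = list(settings = settingsBlock(overviewSettings),
                  position = posBlock,
                  focus = focusBlock(channel = 1, maxStep = 1)),
    name = "next-overview")
  levels <- list(hierarchyLevel("overview", 1L,
                                callbacks = list(nextOverview)))
  queue <- taskQueue(levels)
  z0 <- .tiltAt(tilt, origin[1], origin[2]) + 2.4
  enqueueTask(queue, acquisitionTask("overview", deepMerge(
    overviewSettings,
    list(stage = list(x = origin[1], y = origin[2], z = z0)))), clock = 0)

  log <- runLoop(queue, levels, microscope,
                 stops = makeStoppingCriterion("max_images", n = rows * cols))
  acq <- logAcquisitions(log)
  fit <- stats::lm(z ~ x + y, data = acq)
  ab <- stats::coef(fit)[c("x", "y")]
  relErr <- abs((ab - tilt[1:2]) / tilt[1:2])
  list(focusMap = acq[, c("x", "y", "z")],
       fit = c(a = unname(ab[1]), b = unname(ab[2])),
       truth = c(a = tilt[1], b = tilt[2]),
       relErr = c(a = unname(relErr[1]), b = unname(relErr[2])),
       log = log)
}

.spotPeak <- function(stack, grid, pos, channelIdx) {
  idx <- physicalToPixel(grid, pos)
  d <- dim(stack)
  k <- round(idx[1]) + 1L; j <- round(idx[2]) + 1L; i <- round(idx[3]) + 1L
  if (k < 1L || k > d[2] || j < 2L || j > d[3] - 1L ||
      i < 2L || i > d[4] - 1L) {
    return(NA_real_)
  }
  max(stack[channelIdx, k, (j - 1L):(j + 1L), (i - 1L):(i + 1L)])
}

#' Benchmark: whole-nucleus STED stacks vs selective pole-tile imaging
#'
#' For each of \code{nNuclei} seeded single-nucleus scenes with pore-like
#' surface spots, two arms are run on identical fresh copies of the scene:
#' (a) one whole-nucleus STED stack, and (b) a confocal cell stack followed by
#' 3D segmentation, pole extraction and six 2 x 2 x 2 um STED tiles at the
#' lateral/axial extremes of the nucleus. Spot brightness is read out at the
#' ground-truth spot positions, depth-normalized per nucleus, and pooled;
#' simulated acquisition times come from the clock model.
#'
#' @param seed integer seed
#' @param nNuclei number of nuclei (independent scenes)
#' @param surfaceSpots pore-like spots per nucleus
#' @return list: \code{perNucleus} (times, volume), \code{stackSpots} and
#'   \code{poleSpots} (depth, normalized brightness), Spearman statistics for
#'   both arms, and \code{allTilesFaster}
#' @export
runBleachingBenchmark <- function(seed, nNuclei = 20, surfaceSpots = 60) {
  detailPixel <- list(x = 0.06, y = 0.06, z = 0.25)
  offset0 <- 2  # detector offset subtracted from peak readouts

  mkScene <- function(i) {
    generateScene(.subSeed(seed, i), nucleusCenters = list(c(25, 25)),
                  extent = c(50, 50), surfaceSpots = surfaceSpots,
                  pairSpots = 0, surfaceChannel = 2L,
                  spotBrightness = 150, bodyBrightness = 120)
  }

  perNucleus <- list()
  stackSpots <- list()
  poleSpots <- list()

  for (i in seq_len(nNuclei)) {
    truth <- mkScene(i)
    nuc <- sceneNuclei(truth)[[1]]
    spots <- sceneSpots(truth)
    zlo <- nuc$center[3] - nuc$semi[3]
    depth <- pmin(1, pmax(0, (spots$z - zlo) / (2 * nuc$semi[3])))

    ## arm A: one whole-nucleus STED stack
    sceneA <- mkScene(i)
    msA <- simulatedMicroscope(sceneA)
    rangeA <- 2 * nuc$semi + 1
    treeA <- list(stage = list(x = nuc$center[1], y = nuc$center[2],
                               z = nuc$center[3]),
                  scan = list(range = list(x = rangeA[1], y = rangeA[2],
                                           z = rangeA[3]),
                              pixel = detailPixel),
                  mode = "sted2d", channels = 2, power = 30, dwell = 1e-5)
    t0 <- clockTime(msA)
    mA <- renderMeasurement(msA, acquisitionTask("detail", treeA),
                            id = sprintf("stack%02d", i))
    stackTime <- clockTime(msA) - t0
    gA <- measurementGrid(mA)
    peakA <- vapply(seq_len(nrow(spots)), function(r) {
      .spotPeak(stacks(mA)[[1]], gA,
                c(x = spots$x[r], y = spots$y[r], z = spots$z[r]), 1L)
    }, numeric(1)) - offset0

    ## arm B: confocal cell stack -> segmentation -> 6 pole tiles
    sceneB <- mkScene(i)
    msB <- simulatedMicroscope(sceneB)
    rangeB <- 2 * nuc$semi + 2
    treeCell <- list(stage = as.list(stats::setNames(nuc$center, .axes)),
                     scan = list(range = list(x = rangeB[1], y = rangeB[2],
                                              z = rangeB[3]),
                                 pixel = list(x = 0.25, y = 0.25, z = 0.5)),
                     mode = "confocal", channels = 1, power = 30,
                     dwell = 1e-5)
    mCell <- renderMeasurement(msB, acquisitionTask("cell", treeCell),
                               id = sprintf("cell%02d", i))
    gCell <- measurementGrid(mCell)
    labels <- segment3d(stacks(mCell)[[1]][1, , , ],
                        intensityThreshold = 60, minVoxels = 50)
    poles <- extractPoles(labels == 1L, gCell, tileSize = 2)
    ## acquire deepest tiles first: the dimmest, most aberrated regions are
    ## recorded before any further exposure of their column
    poles <- poles[order(vapply(poles, function(b) boxCenter(b)[["z"]],
                                numeric(1)), decreasing = TRUE)]

    t0 <- clockTime(msB)
    tiles <- lapply(poles, function(box) {
      sc <- physicalToScan(box, stage = nuc$center, limits = 40, minFov = 2)
      tree <- deepMerge(
        list(stage = as.list(stats::setNames(nuc$center, .axes)),
             scan = list(pixel = detailPixel),
             mode = "sted2d", channels = 2, power = 30, dwell = 1e-5), sc)
      renderMeasurement(msB, acquisitionTask("detail", tree), id = "tile")
    })
    poleTime <- clockTime(msB) - t0

    peakB <- rep(NA_real_, nrow(spots))
    tileOf <- rep(NA_integer_, nrow(spots))
    for (ti in seq_along(tiles)) {
      g <- measurementGrid(tiles[[ti]])
      bx <- gridBox(g)
      for (r in seq_len(nrow(spots))) {
        p <- c(x = spots$x[r], y = spots$y[r], z = spots$z[r])
        if (!is.na(peakB[r]) || !.pointInBox(p, bx)) next
        peakB[r] <- .spotPeak(stacks(tiles[[ti]])[[1]], g, p, 1L) - offset0
        tileOf[r] <- ti
      }
    }

    ## per-nucleus scaling (does not affect the pooled trend statistics)
    okA <- which(!is.na(peakA) & peakA > 0)
    okB <- which(!is.na(peakB) & peakB > 0)
    relA <- peakA / stats::median(peakA[okA])
    relB <- peakB / stats::median(peakB[okB])

    ## per-region medians, as in a per-cell "parts of the stack / tiles"
    ## comparison: depth-bin medians for the whole stack, per-tile medians
    ## for selective imaging
    binsA <- cut(depth[okA], breaks = seq(0, 1.0001, by = 0.2),
                 include.lowest = TRUE)
    medA <- tapply(relA[okA], binsA, stats::median)
    depA <- tapply(depth[okA], binsA, stats::median)
    stackSpots[[i]] <- data.frame(nucleus = i,
                                  depth = as.numeric(depA[!is.na(medA)]),
                                  rel = as.numeric(medA[!is.na(medA)]))
    medB <- tapply(relB[okB], tileOf[okB], stats::median)
    depB <- tapply(depth[okB], tileOf[okB], stats::median)
    poleSpots[[i]] <- data.frame(nucleus = i, depth = as.numeric(depB),
                                 rel = as.numeric(medB))
    perNucleus[[i]] <- data.frame(
      nucleus = i, volume = 4 / 3 * pi * prod(nuc$semi),
      stackTime = stackTime, poleTime = poleTime)
  }

  perNucleus <- do.call(rbind, perNucleus)
  stackSpots <- do.call(rbind, stackSpots)
  poleSpots <- do.call(rbind, poleSpots)
  ctA <- suppressWarnings(stats::cor.test(stackSpots$depth, stackSpots$rel,
                                          method = "spearman",
                                          alternative = "less"))
  ctB <- suppressWarnings(stats::cor.test(poleSpots$depth, poleSpots$rel,
                                          method = "spearman",
                                          alternative = "less"))
  ratio <- perNucleus$stackTime / perNucleus$poleTime
  list(perNucleus = perNucleus, stackSpots = stackSpots,
       poleSpots = poleSpots,
       stackRho = unname(ctA$estimate), stackP = ctA$p.value,
       poleRho = unname(ctB$estimate), poleP = ctB$p.value,
       allTilesFaster = all(perNucleus$poleTime < perNucleus$stackTime),
       speedup = ratio,
       volumeSpeedupRho = suppressWarnings(stats::cor(
         perNucleus$volume, ratio, method = "spearman")))
}

#' Pre-scan gating sweep over sample densities
#'
#' For each density, a two-level pipeline walks a stage grid: a very fast
#' coarse pre-scan (1 um pixel spacing) is acquired at every position, and a
#' proper overview is enqueued only when the pre-scan passes the intensity
#' criterion (50 pixels above 50 counts). Returns the fraction of skipped
#' fields of view against the ground-truth mean nuclei per field of view.
#'
#' @param seed integer seed
#' @param densities nuclei per field-of-view area, one sweep point each
#' @param rows,cols stage grid walked at each density
#' @return list: \code{sweep} data.frame (density, meanNucleiPerFov,
#'   skippedFraction) and the Spearman correlation \code{rho} between skipped
#'   fraction and mean nuclei per field of view
#' @export
runPrescanSweep <- function(seed, densities = c(0.25, 0.5, 1, 2, 4, 8),
                            rows = 5, cols = 5) {
  pitch <- 50
  origin <- c(25, 25)
  prescanSettings <- list(
    mode = "confocal", channels = 1, power = 30, dwell = 1e-5,
    scan = list(range = list(x = 50, y = 50, z = 5),
                pixel = list(x = 1, y = 1, z = 1)))
  overviewSettings <- list(
    mode = "confocal", channels = 1, power = 30, dwell = 1e-5,
    scan = list(range = list(x = 50, y = 50, z = 5),
                pixel = list(x = 0.8, y = 0.8, z = 1)))

  rows_out <- list()
  for (di in seq_along(densities)) {
    d <- densities[di]
    scene <- generateScene(.subSeed(seed, 100 + di), density = d,
                           extent = c(cols * pitch, rows * pitch),
                           bodyBrightness = 120)
    microscope <- simulatedMicroscope(scene)

    gateGen <- acquisitionTaskGenerator(
      "overview",
      blocks = list(gate = prescanGateBlock(channel = 1),
                    settings = settingsBlock(overviewSettings),
                    stage = stagePositionBlock()),
      name = "gated-overview")
    posBlock <- positionBlock("grid", origin = c(origin, 2.5), pitch = pitch,
                              rows = rows, cols = cols)
    posBlock(NULL)
    nextPrescan <- acquisitionTaskGenerator(
      "prescan",
      blocks = list(settings = settingsBlock(prescanSettings),
                    position = posBlock),
      name = "next-prescan")

    levels <- list(
      hierarchyLevel("overview", 1L),
      hierarchyLevel("prescan", 2L, callbacks = list(gateGen, nextPrescan)))
    queue <- taskQueue(levels)
    enqueueTask(queue, acquisitionTask("prescan", deepMerge(
      prescanSettings,
      list(stage = list(x = origin[1], y = origin[2], z = 2.5)))), clock = 0)
    log <- runLoop(queue, levels, microscope)
    acq <- logAcquisitions(log)
    nPre <- sum(acq$level == "prescan")
    nOv <- sum(acq$level == "overview")

    nuclei <- sceneNuclei(scene)
    centers <- acq[acq$level == "prescan", c("x", "y")]
    perFov <- vapply(seq_len(nrow(centers)), function(f) {
      sum(vapply(nuclei, function(n) {
        abs(n$center[1] - centers$x[f]) <= 25 &&
          abs(n$center[2] - centers$y[f]) <= 25
      }, logical(1)))
    }, numeric(1))

    rows_out[[di]] <- data.frame(
      density = d, meanNucleiPerFov = mean(perFov),
      skippedFraction = 1 - nOv / nPre, prescans = nPre, overviews = nOv)
  }
  sweep <- do.call(rbind, rows_out)
  rho <- suppressWarnings(stats::cor(sweep$skippedFraction,
                                     sweep$meanNucleiPerFov,
                                     method = "spearman"))
  list(sweep = sweep, rho = rho)
}

#' Stitched vs unstitched border-nucleus imaging comparison
#'
#' A row of overview tiles with 2 um overlap is imaged over a scene whose
#' nuclei alternate between tile centres and tile borders (border nuclei are
#' wider than the overlap, so they touch the image border of every individual
#' tile and are skipped by border discarding). The same pipeline is run twice
#' on identical fresh scenes: once detecting on single tiles, once on
#' on-the-fly stitched canvases; detail acquisitions are mapped back to
#' ground-truth nuclei.
#'
#' @param seed integer seed
#' @param register use phase-correlation registration while stitching
#' @return list with per-arm imaged nucleus ids, counts, border recovery and
#'   the maximum IoU between persisted detail ROIs (dedup check)
#' @export
runStitchComparison <- function(seed, register = TRUE) {
  pitch <- 48
  tileX <- c(25, 25 + pitch, 25 + 2 * pitch)
  centers <- list(c(25, 25), c(49, 25), c(73, 25), c(97, 25), c(121, 25))
  borderIds <- c(2L, 4L)

  mkScene <- function() {
    generateScene(.subSeed(seed, 7), extent = c(150, 50),
                  nucleusCenters = centers, semiAxesXY = c(4.5, 5.5),
                  bodyBrightness = 120, pairSpots = 0)
  }
  overviewSettings <- list(
    mode = "confocal", channels = 1, power = 30, dwell = 1e-5,
    scan = list(range = list(x = 50, y = 50, z = 6),
                pixel = list(x = 0.4, y = 0.4, z = 1)))
  detailSettings <- list(
    mode = "sted2d", channels = 1, power = 30, dwell = 1e-5,
    scan = list(pixel = list(x = 0.1, y = 0.1, z = 1)))

  runArm <- function(stitch) {
    scene <- mkScene()
    microscope <- simulatedMicroscope(scene)
    store <- measurementStore()
    registry <- roiRegistry(iouThreshold = 0.3)
    selector <- if (stitch) {
      stitchedSelector(store, channel = 1, register = register)
    } else {
      lastImageSelector(channel = 1)
    }
    detailGen <- acquisitionTaskGenerator(
      "detail",
      blocks = list(
        settings = settingsBlock(detailSettings),
        stage = stagePositionBlock(),
        rois = detectionBlock(
          nucleusDetector(intensityThreshold = 60, minPixels = 40,
                          discardBorder = TRUE),
          selector = selector, registry = registry, limits = 60,
          minFov = 2)),
      name = "detail-nuclei")
    posBlock <- positionBlock("list", positions = lapply(tileX, function(x) {
      c(x, 25, 2.5)
    }))
    posBlock(NULL)
    nextOverview <- acquisitionTaskGenerator(
      "overview",
      blocks = list(settings = settingsBlock(overviewSettings),
                    position = posBlock),
      name = "next-overview")
    levels <- list(
      hierarchyLevel("detail", 1L),
      hierarchyLevel("overview", 2L,
                     callbacks = list(detailGen, nextOverview)))
    queue <- taskQueue(levels)
    enqueueTask(queue, acquisitionTask("overview", deepMerge(
      overviewSettings,
      list(stage = list(x = tileX[1], y = 25, z = 2.5)))), clock = 0)
    log <- runLoop(queue, levels, microscope, store = store,
                   registry = registry)
    acq <- logAcquisitions(log)

    details <- Filter(function(it) it$level == "detail", store@state$items)
    nuclei <- sceneNuclei(scene)
    imaged <- vapply(details, function(it) {
      ctr <- boxCenter(it$box)
      hits <- which(vapply(nuclei, function(n) {
        sum(((ctr[1:2] - n$center[1:2]) / n$semi[1:2])^2) <= 1
      }, logical(1)))
      if (length(hits)) hits[1] else NA_integer_
    }, integer(1))
    boxes <- lapply(details, function(it) it$box)
    maxIou <- 0
    if (length(boxes) >= 2L) {
      for (a in seq_len(length(boxes) - 1L)) {
        for (b in (a + 1L):length(boxes)) {
          maxIou <- max(maxIou, boxIou(boxes[[a]], boxes[[b]]))
        }
      }
    }
    list(imaged = sort(unique(imaged[!is.na(imaged)])), maxIou = maxIou,
         nDetails = length(details), log = log)
  }

  st <- runArm(TRUE)
  un <- runArm(FALSE)
  list(stitched = st, unstitched = un,
       stitchedCount = length(st$imaged),
       unstitchedCount = length(un$imaged),
       borderRecovered = intersect(st$imaged, borderIds),
       borderMissedUnstitched = setdiff(borderIds, un$imaged),
       maxDetailIou = max(st$maxIou, un$maxIou))
}

#' Reactive timelapse demo: delay-based search/event imaging
#'
#' A two-level timelapse: slow "search" frames with a long task delay watch a
#' location; when a scripted transient emitter appears, the search callback
#' enqueues higher-priority, short-delay "event" frames that re-arm themselves
#' while the emitter persists and stop when it vanishes, reverting to the slow
#' search rate.
#'
#' @param seed integer seed
#' @param eventStart,eventEnd simulated clock interval of the emitter (s)
#' @param searchDelay,eventDelay task delays of the two levels (s)
#' @param maxTime stop the run at this simulated time (s)
#' @return list: acquisition table, trigger \code{latency} (s), logical
#'   \code{triggered}, \code{revertOk} and \code{eventDuringWindowOnly}
#' @export
runReactiveTimelapse <- function(seed, eventStart = 95, eventEnd = 160,
                                 searchDelay = 30, eventDelay = 2,
                                 maxTime = 260) {
  scene <- generateScene(seed, density = 0, extent = c(50, 50))
  sceneAddEvent(scene, c(25, 25, 2), channel = 1L, brightness = 400,
                tStart = eventStart, tEnd = eventEnd)
  microscope <- simulatedMicroscope(scene)

  searchSettings <- list(
    mode = "confocal", channels = 1, power = 30, dwell = 1e-5,
    scan = list(range = list(x = 20, y = 20, z = 2),
                pixel = list(x = 0.5, y = 0.5, z = 1)))
  eventSettings <- deepMerge(searchSettings, list(
    scan = list(range = list(x = 10, y = 10, z = 2))))

  gate <- function() prescanGateBlock(channel = 1, intensityThreshold = 100,
                                      countThreshold = 3)
  eventGen <- acquisitionTaskGenerator(
    "event",
    blocks = list(gate = gate(), settings = settingsBlock(eventSettings),
                  stage = stagePositionBlock()),
    delay = eventDelay, name = "trigger-event")
  rearmGen <- acquisitionTaskGenerator(
    "event",
    blocks = list(gate = gate(), settings = settingsBlock(eventSettings),
                  stage = stagePositionBlock()),
    delay = eventDelay, name = "rearm-event")
  nextSearch <- acquisitionTaskGenerator(
    "search",
    blocks = list(settings = settingsBlock(searchSettings),
                  stage = stagePositionBlock()),
    delay = searchDelay, name = "next-search")

  levels <- list(
    hierarchyLevel("event", 1L, callbacks = list(rearmGen)),
    hierarchyLevel("search", 2L, callbacks = list(eventGen, nextSearch)))
  queue <- taskQueue(levels)
  enqueueTask(queue, acquisitionTask("search", deepMerge(
    searchSettings, list(stage = list(x = 25, y = 25, z = 2)))), clock = 0)

  log <- runLoop(queue, levels, microscope,
                 stops = makeStoppingCriterion("max_time", t = maxTime))
  acq <- logAcquisitions(log)
  ev <- acq[acq$level == "event", ]
  search <- acq[acq$level == "search", ]
  triggered <- nrow(ev) > 0
  latency <- if (triggered) min(ev$clock) - eventStart else NA_real_
  searchPeriod <- searchDelay + 2  # delay + acquisition + trigger margin
  list(acquisitions = acq,
       triggered = triggered,
       latency = latency,
       withinOnePeriod = triggered && latency <= searchPeriod + eventDelay,
       eventDuringWindowOnly = triggered &&
         all(ev$clock >= eventStart & ev$clock <= eventEnd + searchPeriod),
       revertOk = !any(ev$clock > eventEnd + searchPeriod) &&
         any(search$clock > eventEnd),
       log = log)
}
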