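## Simulated confocal/STED microscope -------------------------------------------
##
## Implements the microscope interface against a VirtualScene: Gaussian-PSF
## rendering of nuclei bodies and point emitters, Poisson + read noise,
## per-spot dose-dependent photobleaching, stage drift, and a simulated
## acquisition clock. Swapping this object for a live adapter is the only
## change needed to run a pipeline on hardware.

#' Optics model of the simulated microscope
#'
#' Per-mode lateral/axial Gaussian PSF sigmas. STED sharpens the lateral
#' (2D depletion) or additionally the axial (3D depletion) extent relative to
#' confocal. \code{depthBroadening} grows the lateral sigma linearly with the
#' emitter's height above the slide surface (refractive mismatch away from the
#' coverslip).
#'
#' @param confocalLateral,confocalAxial confocal sigmas (um)
#' @param sted2dLateral,sted2dAxial 2D-depletion sigmas (um)
#' @param sted3dLateral,sted3dAxial 3D-depletion sigmas (um)
#' @param depthBroadening relative lateral broadening per um depth
#' @param referencePower,referenceDwell power (percent) and dwell (s) at which
#'   scene brightnesses are defined
#' @return an \code{OpticsModel} list
#' @export
opticsModel <- function(confocalLateral = 0.11, confocalAxial = 0.30,
                        sted2dLateral = 0.035, sted2dAxial = 0.30,
                        sted3dLateral = 0.045, sted3dAxial = 0.10,
                        depthBroadening = 0.01, referencePower = 30,
                        referenceDwell = 1e-5) {
  stopifnot(sted2dLateral < confocalLateral,
            sted3dLateral < confocalLateral,
            sted3dAxial < confocalAxial)
  structure(list(
    sigma = list(
      confocal = c(lat = confocalLateral, ax = confocalAxial),
      sted2d = c(lat = sted2dLateral, ax = sted2dAxial),
      sted3d = c(lat = sted3dLateral, ax = sted3dAxial)),
    depthBroadening = depthBroadening,
    referencePower = referencePower,
    referenceDwell = referenceDwell), class = "OpticsModel")
}

#' Acquisition clock model
#'
#' Point-scanning acquisition time scales with the number of voxels imaged
#' (dwell time per pixel) plus per-line, per-frame and per-measurement
#' overheads and stage travel time -- the reason selective small-region
#' imaging is faster than whole-volume stacks.
#'
#' @param perLine seconds per scanned line (flyback)
#' @param perFrame seconds per z-plane (settling)
#' @param perMeasurement seconds per configuration (setup)
#' @param stageMovePerUm seconds per um of stage travel
#' @return a \code{ClockModel} list
#' @export
clockModel <- function(perLine = 2e-4, perFrame = 0.02, perMeasurement = 0.3,
                       stageMovePerUm = 0.01) {
  structure(list(perLine = perLine, perFrame = perFrame,
                 perMeasurement = perMeasurement,
                 stageMovePerUm = stageMovePerUm), class = "ClockModel")
}

#' Photobleaching dose model
#'
#' Scanning one z-plane delivers illumination dose to every emitter in the
#' scanned xy column: the excitation/depletion light traverses the whole
#' depth, which is what builds up the along-stack bleaching gradient in
#' whole-volume stacks. Optionally the dose can be attenuated with axial
#' distance from the focal plane, \code{rate / (1 + (dz / axialRange)^2)};
#' the default is a uniform column (\code{axialRange = Inf}), adequate on the
#' few-micron scale of a nucleus. Doses are multiplied by the power and dwell
#' scale factors; the depletion beam makes a STED exposure far more damaging
#' than a confocal one. Remaining brightness multiplies by \code{exp(-dose)}.
#'
#' @param confocal,sted2d,sted3d in-focus dose rate per plane exposure
#' @param axialRange axial half-width of the dose profile (um)
#' @return a \code{BleachModel} list
#' @export
bleachRates <- function(confocal = 4e-4, sted2d = 0.022, sted3d = 0.022,
                        axialRange = Inf) {
  structure(list(rates = c(confocal = confocal, sted2d = sted2d,
                           sted3d = sted3d),
                 axialRange = axialRange), class = "BleachModel")
}

#' Duration of one acquisition under the clock model
#'
#' @param clock a \code{ClockModel}
#' @param grid the \linkS4class{PixelGrid} scanned
#' @param dwell pixel dwell time (s)
#' @param stageDist stage travel distance to reach the position (um)
#' @return seconds
#' @export
acquisitionDuration <- function(clock, grid, dwell, stageDist = 0) {
  nz <- grid@shape[["z"]]; ny <- grid@shape[["y"]]; nx <- grid@shape[["x"]]
  clock$perMeasurement + nz * clock$perFrame + nz * ny * clock$perLine +
    nz * ny * nx * dwell + stageDist * clock$stageMovePerUm
}

#' Create a simulated microscope
#'
#' @param scene a \linkS4class{VirtualScene}
#' @param optics an \code{OpticsModel}
#' @param clock a \code{ClockModel}
#' @param bleach per-mode dose rates from \code{\link{bleachRates}}
#' @param readNoise Gaussian read-noise sigma (counts)
#' @param offset detector offset added to every pixel (counts)
#' @return a \linkS4class{SimulatedMicroscope}
#' @export
simulatedMicroscope <- function(scene, optics = opticsModel(),
                                clock = clockModel(),
                                bleach = bleachRates(),
                                readNoise = 1, offset = 2) {
  st <- new.env(parent = emptyenv())
  st$scene <- scene
  st$optics <- optics
  st$clock <- clock
  st$bleach <- bleach
  st$readNoise <- readNoise
  st$offset <- offset
  st$t <- 0
  st$pending <- NULL
  st$lastStage <- NULL
  st$counter <- 0L
  new("SimulatedMicroscope", state = st)
}

#' @rdname microscope-interface
setMethod("applyParameters", "SimulatedMicroscope", function(microscope,
                                                             parameters) {
  validateParameterTree(parameters)
  microscope@state$pending <- parameters
  invisible(microscope)
})

#' @rdname microscope-interface
setMethod("clockTime", "SimulatedMicroscope", function(microscope) {
  microscope@state$t
})

#' @rdname microscope-interface
setMethod("waitUntil", "SimulatedMicroscope", function(microscope, time) {
  microscope@state$t <- max(microscope@state$t, time)
  invisible(microscope)
})

#' @rdname microscope-interface
setMethod("acquireFrame", "SimulatedMicroscope", function(microscope) {
  st <- microscope@state
  tree <- st$pending
  if (is.null(tree)) stop("no parameters applied", call. = FALSE)
  grid <- pixelGridFromParameters(tree)
  dwell <- treeGet(tree, "dwell") %||% st$optics$referenceDwell
  stage <- c(x = treeGet(tree, "stage/x"), y = treeGet(tree, "stage/y"),
             z = treeGet(tree, "stage/z"))
  dist <- if (is.null(st$lastStage)) 0 else {
    sqrt(sum((stage - st$lastStage)^2))
  }
  st$lastStage <- stage

  drift <- driftAt(st$scene, st$t)
  expected <- .expectedStack(st$scene@state, grid, tree, st$optics, drift,
                             clock = st$t, bleachRates = st$bleach,
                             applyBleach = TRUE)
  st$counter <- st$counter + 1L
  counts <- withSeed(.subSeed(st$scene@state$seed, st$counter), {
    n <- length(expected)
    cnt <- stats::rpois(n, lambda = as.numeric(expected)) +
      round(stats::rnorm(n, sd = st$readNoise)) + st$offset
    pmin(pmax(cnt, 0), 65535)  # 16-bit with saturation
  })
  out <- array(as.numeric(counts), dim = dim(expected))

  st$t <- st$t + acquisitionDuration(st$clock, grid, dwell, dist)
  out
})

#' Acquire a full task on a microscope, outside the main loop
#'
#' Applies and acquires every configuration of \code{task} and wraps the
#' result as a \linkS4class{Measurement}; convenient for scripted experiments
#' and benchmarks that do not need the scheduler.
#'
#' @param microscope a microscope backend
#' @param task an \linkS4class{AcquisitionTask}
#' @param id measurement id to assign
#' @return a \linkS4class{Measurement}
#' @export
renderMeasurement <- function(microscope, task, id = "adhoc") {
  stacks <- vector("list", length(configurations(task)))
  for (i in seq_along(configurations(task))) {
    applyParameters(microscope, parameters(configurations(task)[[i]]))
    stacks[[i]] <- acquireFrame(microscope)
  }
  new("Measurement", id = id, levelId = levelId(task),
      sequence = if (is.na(task@sequence)) 0L else task@sequence,
      configurations = configurations(task), stacks = stacks,
      acquiredAt = clockTime(microscope), parentId = task@parentId)
}

#' Noise-free expected-photon image of one configuration
#'
#' Renders the deterministic expected-count stack for the given parameters
#' (no Poisson/read noise, no bleach-state update, no drift); the reference
#' for resolution and linearity checks.
#'
#' @param scene a \linkS4class{VirtualScene}
#' @param parameters a parameter tree
#' @param optics an \code{OpticsModel}
#' @return a 4D array \code{[channel, z, y, x]} of expected counts
#' @export
renderExpectedImage <- function(scene, parameters, optics = opticsModel()) {
  grid <- pixelGridFromParameters(parameters)
  .expectedStack(scene@state, grid, parameters, optics,
                 drift = c(x = 0, y = 0, z = 0), clock = 0,
                 bleachRates = bleachRates(), applyBleach = FALSE)
}

## The renderer ---------------------------------------------------------------
## Scan order: z planes from the coverslip upward; within a plane the photon
## expectation is evaluated on the full pixel lattice. Each plane exposure
## delivers illumination dose to every emitter in the scanned xy column
## (the excitation/depletion cone traverses the whole depth), which is what
## builds up the along-stack bleaching gradient in whole-volume stacks.
.expectedStack <- function(ss, grid, tree, optics, drift, clock,
                           bleachRates, applyBleach) {
  mode <- tree$mode %||% "confocal"
  if (!mode %in% names(optics$sigma)) {
    stop(sprintf("unknown imaging mode '%s'", mode), call. = FALSE)
  }
  power <- tree$power %||% optics$referencePower
  dwell <- tree$dwell %||% optics$referenceDwell
  channels <- as.integer(tree$channels %||% 1L)
  scale <- (power / optics$referencePower) * (dwell / optics$referenceDwell)

  nx <- grid@shape[["x"]]; ny <- grid@shape[["y"]]; nz <- grid@shape[["z"]]
  ctr <- grid@stage + grid@offset
  xs <- ctr[["x"]] - grid@range[["x"]] / 2 + (seq_len(nx) - 0.5) * grid@pixel[["x"]]
  ys <- ctr[["y"]] - grid@range[["y"]] / 2 + (seq_len(ny) - 0.5) * grid@pixel[["y"]]
  zs <- ctr[["z"]] - grid@range[["z"]] / 2 + (seq_len(nz) - 0.5) * grid@pixel[["z"]]

  sig <- optics$sigma[[mode]]
  out <- array(0, dim = c(length(channels), nz, ny, nx))

  ## nuclei bodies (apparent position = true + drift)
  bodyIdx <- match(ss$bodyChannel, channels)
  nucs <- ss$nuclei
  if (!is.na(bodyIdx) && length(nucs)) {
    nucs <- Filter(function(n) {
      c0 <- n$center[1:2] + drift[c("x", "y")]
      c0[1] + n$semi[1] > xs[1] - 1 && c0[1] - n$semi[1] < xs[nx] + 1 &&
        c0[2] + n$semi[2] > ys[1] - 1 && c0[2] - n$semi[2] < ys[ny] + 1
    }, nucs)
  } else {
    nucs <- list()
  }

  ## emitters: regular spots plus active transient events
  spots <- ss$spots
  active <- integer(0)
  if (nrow(spots)) {
    active <- which(spots$channel %in% channels &
                    spots$x + drift[["x"]] > xs[1] - 2 &
                    spots$x + drift[["x"]] < xs[nx] + 2 &
                    spots$y + drift[["y"]] > ys[1] - 2 &
                    spots$y + drift[["y"]] < ys[ny] + 2)
  }
  ev <- ss$events
  evRows <- if (nrow(ev)) {
    which(ev$tStart <= clock & clock < ev$tEnd & ev$channel %in% channels)
  } else integer(0)

  emitters <- rbind(
    if (length(active)) {
      data.frame(x = spots$x[active], y = spots$y[active],
                 z = spots$z[active], channel = spots$channel[active],
                 amp = spots$brightness[active] * spots$remaining[active],
                 size = 0)
    },
    if (length(evRows)) {
      data.frame(x = ev$x[evRows], y = ev$y[evRows], z = ev$z[evRows],
                 channel = ev$channel[evRows], amp = ev$brightness[evRows],
                 size = ev$size[evRows] %||% 0.8)
    })

  emLat <- emAx <- numeric(0)
  if (!is.null(emitters) && nrow(emitters)) {
    depth <- pmax(0, emitters$z - .tiltAt(ss$tilt, emitters$x, emitters$y))
    ## image extent = PSF convolved with the emitter's own spatial extent
    emLat <- sqrt((sig[["lat"]] * (1 + optics$depthBroadening * depth))^2 +
                  emitters$size^2)
    emAx <- sqrt(sig[["ax"]]^2 + emitters$size^2)
  }

  dosePerPlane <- bleachRates$rates[[mode]] * scale
  zR <- bleachRates$axialRange

  for (k in seq_len(nz)) {
    zk <- zs[k]
    for (ci in seq_along(channels)) {
      plane <- matrix(0, ny, nx)
      if (length(nucs) && !is.na(bodyIdx) && ci == bodyIdx) {
        for (n in nucs) {
          c0 <- n$center + drift
          if (abs(zk - c0[3]) > n$semi[3]) next
          ex <- ((xs - c0[1]) / n$semi[1])^2
          ey <- ((ys - c0[2]) / n$semi[2])^2
          ez <- ((zk - c0[3]) / n$semi[3])^2
          e <- outer(ey, ex, "+") + ez
          w <- pmin(1, pmax(0, (1 - e) / 0.15))
          plane <- plane + n$body * scale * w
        }
      }
      if (!is.null(emitters) && nrow(emitters)) {
        rows <- which(emitters$channel == channels[ci])
        for (r in rows) {
          sl <- emLat[r]
          sa <- emAx[r]
          dz <- zk - (emitters$z[r] + drift[["z"]])
          if (abs(dz) > 4 * sa) next
          sx <- emitters$x[r] + drift[["x"]]
          sy <- emitters$y[r] + drift[["y"]]
          ii <- which(abs(xs - sx) <= 4 * sl)
          jj <- which(abs(ys - sy) <= 4 * sl)
          if (!length(ii) || !length(jj)) next
          amp <- emitters$amp[r] * scale * exp(-dz^2 / (2 * sa^2))
          gx <- exp(-(xs[ii] - sx)^2 / (2 * sl^2))
          gy <- exp(-(ys[jj] - sy)^2 / (2 * sl^2))
          plane[jj, ii] <- plane[jj, ii] + amp * outer(gy, gx)
        }
      }
      out[ci, k, , ] <- plane
    }
    if (applyBleach && nrow(spots) && dosePerPlane > 0) {
      exposed <- which(spots$x + drift[["x"]] >= xs[1] - grid@pixel[["x"]] / 2 &
                       spots$x + drift[["x"]] <= xs[nx] + grid@pixel[["x"]] / 2 &
                       spots$y + drift[["y"]] >= ys[1] - grid@pixel[["y"]] / 2 &
                       spots$y + drift[["y"]] <= ys[ny] + grid@pixel[["y"]] / 2)
      if (length(exposed)) {
        dz <- (spots$z[exposed] + drift[["z"]]) - zk
        dose <- dosePerPlane / (1 + (dz / zR)^2)
        ss$spots$remaining[exposed] <-
          ss$spots$remaining[exposed] * exp(-dose)
        spots <- ss$spots
        ## emitter amplitudes in later planes must see the updated state
        if (length(active)) {
          emitters$amp[seq_along(active)] <-
            spots$brightness[active] * spots$remaining[active]
        }
      }
    }
  }
  out
}
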