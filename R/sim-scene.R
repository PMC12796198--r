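## Virtual scenes: the ground-truth sample for the simulated microscope --------

## run expr with a local RNG seed, leaving the caller's RNG state untouched
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

## deterministic sub-seed streams derived from a base seed and a counter
.subSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %%
             2147483647)
}

.tiltAt <- function(tilt, x, y) tilt[1] * x + tilt[2] * y + tilt[3]

#' Construct a virtual scene explicitly
#'
#' Lower-level companion of \code{\link{generateScene}}: nuclei, spots and
#' events are supplied directly. Nuclei are axis-aligned ellipsoids resting on
#' the (possibly tilted) slide surface, carrying a diffuse body stain; spots
#' are point emitters with a per-spot remaining-brightness fraction that only
#' decreases as illumination dose accumulates.
#'
#' @param seed integer seed driving all scene randomness (noise, drift)
#' @param extent slide extent (x, y) in um
#' @param tilt tilt-plane coefficients (a, b, c): slide surface
#'   \code{z = a x + b y + c} (um)
#' @param nuclei list of nuclei; each
#'   \code{list(center = c(x, y, z), semi = c(ax, ay, az), body = counts)}
#' @param spots data.frame with columns x, y, z, channel, brightness,
#'   remaining, nucleus
#' @param events data.frame of transient emitters with columns x, y, z,
#'   channel, brightness, tStart, tEnd (appear only while
#'   \code{tStart <= clock < tEnd})
#' @param drift list: \code{sigmaRw} (um per sqrt minute, random walk),
#'   \code{amplitude} and \code{period} (um, s: thermal oscillation)
#' @param bodyChannel channel carrying the nucleus body stain
#' @return a \linkS4class{VirtualScene}
#' @export
virtualScene <- function(seed, extent = c(250, 250), tilt = c(0, 0, 0),
                         nuclei = list(), spots = NULL, events = NULL,
                         drift = list(sigmaRw = 0, amplitude = 0,
                                      period = 600),
                         bodyChannel = 1L) {
  s <- new.env(parent = emptyenv())
  s$seed <- as.integer(seed)
  s$extent <- as.numeric(extent)
  s$tilt <- as.numeric(tilt)
  s$nuclei <- nuclei
  s$spots <- spots %||% data.frame(x = numeric(0), y = numeric(0),
                                   z = numeric(0), channel = integer(0),
                                   brightness = numeric(0),
                                   remaining = numeric(0),
                                   nucleus = integer(0))
  s$events <- events %||% data.frame(x = numeric(0), y = numeric(0),
                                     z = numeric(0), channel = integer(0),
                                     brightness = numeric(0),
                                     size = numeric(0),
                                     tStart = numeric(0), tEnd = numeric(0))
  if (nrow(s$events) && is.null(s$events$size)) s$events$size <- 0.8
  s$drift <- list(sigmaRw = drift$sigmaRw %||% 0,
                  amplitude = drift$amplitude %||% 0,
                  period = drift$period %||% 600)
  s$bodyChannel <- as.integer(bodyChannel)
  s$rngCounter <- 0L
  s$driftT <- 0
  s$driftRw <- c(x = 0, y = 0, z = 0)
  s$driftCounter <- 0L
  new("VirtualScene", state = s)
}

#' Generate a randomized virtual scene
#'
#' Nuclei are placed by a seeded Poisson point process over the slide
#' (expected count = \code{density * slide area / fovSize^2}), rejecting
#' overlaps. Each nucleus is an axis-aligned ellipsoid resting on the tilted
#' slide surface and may carry pore-like surface spots (sampled on the
#' ellipsoid shell) and/or colocalizing two-channel FISH-like interior spot
#' pairs. Identical seeds give identical scenes.
#'
#' @param seed integer seed
#' @param density expected nuclei per field-of-view area
#' @param extent slide extent (x, y) in um
#' @param fovSize reference field-of-view side (um) defining the density unit
#' @param semiAxesXY,semiAxesZ uniform ranges for the lateral / axial
#'   semi-axes (um)
#' @param surfaceSpots pore-like surface spots per nucleus (on
#'   \code{surfaceChannel})
#' @param pairSpots colocalizing two-channel spot pairs per nucleus
#' @param pairChannels the two channels of a pair
#' @param pairSeparation distance between pair partners (um)
#' @param surfaceChannel channel of the surface spots
#' @param spotBrightness expected peak counts of a spot at reference
#'   power/dwell
#' @param bodyBrightness expected body-stain counts per voxel at reference
#'   settings
#' @param tilt tilt-plane coefficients (a, b, c)
#' @param drift drift model, see \code{\link{virtualScene}}
#' @param nucleusCenters optional list of (x, y) centres overriding the point
#'   process (sizes and spots still randomized)
#' @return a \linkS4class{VirtualScene}
#' @export
generateScene <- function(seed, density = 1, extent = c(250, 250),
                          fovSize = 50, semiAxesXY = c(4, 6),
                          semiAxesZ = c(2, 3), surfaceSpots = 0,
                          pairSpots = 0, pairChannels = c(2, 3),
                          pairSeparation = 0.08, surfaceChannel = 2L,
                          spotBrightness = 150, bodyBrightness = 120,
                          tilt = c(0, 0, 0),
                          drift = list(sigmaRw = 0, amplitude = 0,
                                       period = 600),
                          nucleusCenters = NULL) {
  stopifnot(density >= 0)
  withSeed(seed, {
    if (is.null(nucleusCenters)) {
      lambda <- density * prod(extent) / fovSize^2
      n <- stats::rpois(1, lambda)
      centersXY <- list()
      tries <- 0L
      maxSemi <- max(semiAxesXY)
      while (length(centersXY) < n && tries < n * 50L) {
        tries <- tries + 1L
        cand <- c(stats::runif(1, 0, extent[1]), stats::runif(1, 0, extent[2]))
        ok <- all(vapply(centersXY, function(p) {
          sum((p - cand)^2) > (2 * maxSemi)^2
        }, logical(1)))
        if (ok) centersXY[[length(centersXY) + 1L]] <- cand
      }
    } else {
      centersXY <- lapply(nucleusCenters, function(p) as.numeric(p[1:2]))
    }

    nuclei <- list()
    spotRows <- list()
    for (i in seq_along(centersXY)) {
      xy <- centersXY[[i]]
      semi <- c(stats::runif(2, semiAxesXY[1], semiAxesXY[2]),
                stats::runif(1, semiAxesZ[1], semiAxesZ[2]))
      cz <- .tiltAt(tilt, xy[1], xy[2]) + semi[3]  # resting on the slide
      center <- c(xy, cz)
      nuclei[[i]] <- list(center = center, semi = semi,
                          body = bodyBrightness)
      if (surfaceSpots > 0) {
        u <- matrix(stats::rnorm(3 * surfaceSpots), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        pos <- sweep(u %*% diag(semi), 2, center, "+")
        spotRows[[length(spotRows) + 1L]] <- data.frame(
          x = pos[, 1], y = pos[, 2], z = pos[, 3],
          channel = as.integer(surfaceChannel),
          brightness = spotBrightness * stats::rlnorm(surfaceSpots,
                                                      sdlog = 0.15),
          remaining = 1, nucleus = i)
      }
      if (pairSpots > 0) {
        for (p in seq_len(pairSpots)) {
          repeat {
            u <- stats::runif(3, -1, 1)
            if (sum(u^2) <= 1) break
          }
          base <- center + u * semi * 0.7
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2)) * pairSeparation / 2
          bright <- spotBrightness * stats::rlnorm(2, sdlog = 0.15)
          spotRows[[length(spotRows) + 1L]] <- data.frame(
            x = base[1] + c(dir[1], -dir[1]),
            y = base[2] + c(dir[2], -dir[2]),
            z = base[3] + c(dir[3], -dir[3]),
            channel = as.integer(pairChannels),
            brightness = bright, remaining = 1, nucleus = i)
        }
      }
    }
    spots <- if (length(spotRows)) do.call(rbind, spotRows) else NULL
    virtualScene(seed = seed, extent = extent, tilt = tilt, nuclei = nuclei,
                 spots = spots, drift = drift)
  })
}

#' Add a transient event emitter to a scene
#'
#' The emitter is rendered only while \code{tStart <= clock < tEnd}; used to
#' script reactive-timelapse scenarios.
#'
#' @param scene a \linkS4class{VirtualScene}
#' @param position numeric (x, y, z) in um
#' @param channel detection channel
#' @param brightness expected peak counts at reference settings
#' @param size spatial Gaussian extent of the event structure (um); events
#'   are extended objects (a transient signalling region, a fusing vesicle
#'   neighbourhood), not diffraction-limited points
#' @param tStart,tEnd clock interval (s) during which the emitter exists
#' @return the scene, invisibly
#' @export
sceneAddEvent <- function(scene, position, channel = 1L, brightness = 300,
                          size = 0.8, tStart = 0, tEnd = Inf) {
  s <- scene@state
  s$events <- rbind(s$events, data.frame(
    x = position[1], y = position[2], z = position[3],
    channel = as.integer(channel), brightness = brightness, size = size,
    tStart = tStart, tEnd = tEnd))
  invisible(scene)
}

#' Ground-truth nuclei of a scene
#' @param scene a \linkS4class{VirtualScene}
#' @return list of nuclei (center, semi, body)
#' @export
sceneNuclei <- function(scene) scene@state$nuclei

#' Ground-truth spot table of a scene
#' @param scene a \linkS4class{VirtualScene}
#' @return data.frame (x, y, z, channel, brightness, remaining, nucleus)
#' @export
sceneSpots <- function(scene) scene@state$spots

#' Stage drift at a clock time
#'
#' Sum of a seeded random walk (sigma \code{sigmaRw} um per sqrt minute,
#' advanced between successive query times) and a deterministic sinusoidal
#' thermal component that vanishes at t = 0. Deterministic given the scene
#' seed and the sequence of query times; query times must be non-decreasing.
#'
#' @param scene a \linkS4class{VirtualScene}
#' @param t clock time (s), >= the previous query
#' @return named numeric (x, y, z) offset in um
#' @export
driftAt <- function(scene, t) {
  s <- scene@state
  stopifnot(t >= 0)
  if (t < s$driftT) stop("drift query times must be non-decreasing",
                         call. = FALSE)
  if (t > s$driftT && s$drift$sigmaRw > 0) {
    dt <- t - s$driftT
    s$driftCounter <- s$driftCounter + 1L
    step <- withSeed(.subSeed(s$seed + 1000L, s$driftCounter), {
      stats::rnorm(3, sd = s$drift$sigmaRw * sqrt(dt / 60))
    })
    s$driftRw <- s$driftRw + c(x = step[1], y = step[2], z = step[3])
  }
  s$driftT <- max(s$driftT, t)
  th <- 2 * pi * t / s$drift$period
  thermal <- s$drift$amplitude * c(x = sin(th), y = cos(th) - 1, z = 0)
  s$driftRw + thermal
}

#' Photobleaching survival factor
#'
#' Multiplicative remaining-brightness factor after an illumination dose:
#' \code{exp(-k * dose)}; multiplicative over sequential exposures.
#'
#' @param k bleach rate per unit dose (>= 0)
#' @param dose accumulated illumination dose (>= 0)
#' @return multiplier in (0, 1]
#' @export
bleachFactor <- function(k, dose) {
  stopifnot(k >= 0, all(dose >= 0))
  exp(-k * dose)
}

#' Serialize / restore a virtual scene as JSON
#'
#' Captures the full ground truth, including the mutable bleach state, so a
#' scene written right after generation round-trips byte-identically for the
#' same seed.
#'
#' @param scene a \linkS4class{VirtualScene}
#' @param path file path
#' @return \code{writeScene}: the path invisibly; \code{readScene}: a
#'   \linkS4class{VirtualScene}
#' @export
writeScene <- function(scene, path) {
  s <- scene@state
  nucTable <- if (length(s$nuclei)) {
    do.call(rbind, lapply(s$nuclei, function(n) {
      data.frame(cx = n$center[1], cy = n$center[2], cz = n$center[3],
                 ax = n$semi[1], ay = n$semi[2], az = n$semi[3],
                 body = n$body)
    }))
  } else NULL
  obj <- list(seed = s$seed, extent = s$extent, tilt = s$tilt,
              bodyChannel = s$bodyChannel, drift = s$drift,
              nuclei = nucTable, spots = s$spots, events = s$events)
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE,
                                           null = "null", dataframe = "rows")),
             path)
  invisible(path)
}

#' @rdname writeScene
#' @export
readScene <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"),
                            simplifyVector = TRUE, simplifyDataFrame = TRUE)
  nt <- obj$nuclei
  nuclei <- if (is.data.frame(nt) && nrow(nt)) {
    lapply(seq_len(nrow(nt)), function(i) {
      list(center = c(nt$cx[i], nt$cy[i], nt$cz[i]),
           semi = c(nt$ax[i], nt$ay[i], nt$az[i]),
           body = nt$body[i])
    })
  } else list()
  spots <- if (is.data.frame(obj$spots) && nrow(obj$spots)) obj$spots else NULL
  events <- if (is.data.frame(obj$events) && nrow(obj$events)) obj$events
            else NULL
  virtualScene(seed = obj$seed, extent = obj$extent, tilt = obj$tilt,
               nuclei = nuclei, spots = spots, events = events,
               drift = obj$drift, bodyChannel = obj$bodyChannel)
}
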