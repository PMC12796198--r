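## S4 classes -----------------------------------------------------------------

#' Configuration: one named parameter variant within an acquisition task
#'
#' A measurement can consist of several configurations (e.g. the same location
#' imaged with 2D and 3D depletion patterns back-to-back); each carries its own
#' complete parameter tree.
#'
#' @slot name non-empty configuration name, unique within a task
#' @slot parameters a parameter tree (nested named list)
#' @export
setClass("Configuration",
  representation(name = "character", parameters = "list"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name)) {
      return("configuration name must be a non-empty string")
    }
    TRUE
  })

#' Create a Configuration
#' @param name configuration name
#' @param parameters parameter tree
#' @return a \linkS4class{Configuration}
#' @export
configuration <- function(name, parameters) {
  validateParameterTree(parameters)
  new("Configuration", name = name, parameters = parameters)
}

#' AcquisitionTask: one queued unit of imaging work
#'
#' @slot levelId name of the hierarchy level the task belongs to
#' @slot sequence monotone integer assigned at enqueue time (NA before)
#' @slot configurations list of \linkS4class{Configuration} (at least one)
#' @slot delay seconds to wait before the task becomes eligible
#' @slot eligibleTime clock seconds at which the task may be popped
#'   (enqueue clock + delay; NA before enqueue)
#' @slot parentId id of the measurement whose callback created the task,
#'   or NA
#' @export
setClass("AcquisitionTask",
  representation(levelId = "character", sequence = "integer",
                 configurations = "list", delay = "numeric",
                 eligibleTime = "numeric", parentId = "character"),
  validity = function(object) {
    if (length(object@configurations) < 1L) {
      return("a task needs at least one configuration")
    }
    if (!all(vapply(object@configurations, is, logical(1), "Configuration"))) {
      return("configurations must be Configuration objects")
    }
    nms <- vapply(object@configurations, function(cf) cf@name, character(1))
    if (anyDuplicated(nms)) {
      return("configuration names must be unique within a task")
    }
    if (object@delay < 0) return("delay must be >= 0")
    TRUE
  })

#' Create an AcquisitionTask
#'
#' \code{sequence} and \code{eligibleTime} are assigned when the task is
#' enqueued (see \code{\link{enqueueTask}}).
#'
#' @param levelId hierarchy level name
#' @param configurations list of \linkS4class{Configuration}, or a single
#'   parameter tree (wrapped as configuration \code{"main"})
#' @param delay seconds (>= 0) before the task becomes eligible
#' @param parentId optional parent measurement id
#' @return an \linkS4class{AcquisitionTask}
#' @export
acquisitionTask <- function(levelId, configurations, delay = 0,
                            parentId = NA_character_) {
  if (.isSubtree(configurations)) {
    configurations <- list(configuration("main", configurations))
  }
  new("AcquisitionTask", levelId = levelId, sequence = NA_integer_,
      configurations = configurations, delay = as.numeric(delay),
      eligibleTime = NA_real_, parentId = parentId)
}

#' HierarchyLevel: a named pipeline tier with a priority rank and callbacks
#'
#' Lower rank means higher priority: detail levels (rank 1) preempt overview
#' levels (rank 2).
#'
#' @slot name level name
#' @slot rank integer priority rank (lower = popped first)
#' @slot callbacks ordered list of callbacks run after each acquisition on
#'   this level; each is either an \linkS4class{AcquisitionTaskGenerator} or a
#'   function of the loop state
#' @export
setClass("HierarchyLevel",
  representation(name = "character", rank = "integer", callbacks = "list"),
  validity = function(object) {
    if (!nzchar(object@name)) return("level name must be non-empty")
    TRUE
  })

#' Create a HierarchyLevel
#' @param name level name
#' @param rank integer priority rank (lower = higher priority)
#' @param callbacks list of callbacks (generators or functions of state)
#' @return a \linkS4class{HierarchyLevel}
#' @export
hierarchyLevel <- function(name, rank, callbacks = list()) {
  new("HierarchyLevel", name = name, rank = as.integer(rank),
      callbacks = callbacks)
}

#' Measurement: acquired image stacks plus full provenance
#'
#' @slot id measurement identifier
#' @slot levelId hierarchy level the measurement was acquired on
#' @slot sequence queue sequence number of the originating task
#' @slot configurations list of \linkS4class{Configuration} (full merged
#'   parameter trees)
#' @slot stacks one 4D array per configuration, indexed
#'   \code{[channel, z, y, x]}
#' @slot acquiredAt simulated/wall clock seconds at completion
#' @slot parentId id of the parent measurement, or NA
#' @export
setClass("Measurement",
  representation(id = "character", levelId = "character",
                 sequence = "integer", configurations = "list",
                 stacks = "list", acquiredAt = "numeric",
                 parentId = "character"),
  validity = function(object) {
    if (length(object@stacks) != length(object@configurations)) {
      return("number of stacks must equal number of configurations")
    }
    TRUE
  })

#' PhysicalBox: an axis-aligned box in stage coordinates (um)
#'
#' @slot minCorner named numeric (x, y, z), lower corner
#' @slot maxCorner named numeric (x, y, z), upper corner
#' @export
setClass("PhysicalBox",
  representation(minCorner = "numeric", maxCorner = "numeric"),
  validity = function(object) {
    if (length(object@minCorner) != 3L || length(object@maxCorner) != 3L) {
      return("corners must have length 3 (x, y, z)")
    }
    if (any(!is.finite(object@minCorner)) || any(!is.finite(object@maxCorner))) {
      return("corners must be finite")
    }
    if (any(object@minCorner > object@maxCorner)) {
      return("min corner must be <= max corner on every axis")
    }
    TRUE
  })

.axes <- c("x", "y", "z")

.asAxisVec <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 3L)
  names(v) <- .axes
  v
}

#' Create a PhysicalBox
#' @param minCorner,maxCorner numeric length-3 (x, y, z) in um
#' @return a \linkS4class{PhysicalBox}
#' @export
physicalBox <- function(minCorner, maxCorner) {
  new("PhysicalBox", minCorner = .asAxisVec(minCorner),
      maxCorner = .asAxisVec(maxCorner))
}

#' Create a PhysicalBox from its center and edge lengths
#' @param center numeric length-3 (x, y, z) in um
#' @param size numeric length-3 (or scalar) edge lengths in um
#' @return a \linkS4class{PhysicalBox}
#' @export
boxFromCenter <- function(center, size) {
  center <- .asAxisVec(center)
  size <- .asAxisVec(if (length(size) == 1L) rep(size, 3L) else size)
  physicalBox(center - size / 2, center + size / 2)
}

#' PixelGrid: the mapping between pixel indices and stage coordinates
#'
#' The grid is centred at \code{stage + offset}; along each axis the physical
#' coordinate of (0-based, possibly fractional) pixel index i is
#' \code{stage + offset - range/2 + (i + 0.5) * pixel} (pixel-centre
#' convention). Arrays are stored \code{[z, y, x]}.
#'
#' @slot stage named numeric (x, y, z) stage position, um
#' @slot offset named numeric (x, y, z) scan offsets, um
#' @slot range named numeric (x, y, z) scan ranges, um
#' @slot pixel named numeric (x, y, z) pixel sizes, um
#' @slot shape named integer (x, y, z), \code{round(range / pixel)}
#' @export
setClass("PixelGrid",
  representation(stage = "numeric", offset = "numeric", range = "numeric",
                 pixel = "numeric", shape = "integer"),
  validity = function(object) {
    if (any(object@pixel <= 0)) return("pixel sizes must be > 0")
    if (any(object@range <= 0)) return("scan ranges must be > 0")
    if (any(object@shape < 1L)) return("grid shape must be >= 1 per axis")
    TRUE
  })

#' Create a PixelGrid
#' @param stage,offset,range,pixel numeric length-3 (x, y, z) in um
#' @return a \linkS4class{PixelGrid}
#' @export
pixelGrid <- function(stage, offset, range, pixel) {
  stage <- .asAxisVec(stage); offset <- .asAxisVec(offset)
  range <- .asAxisVec(range); pixel <- .asAxisVec(pixel)
  if (any(!is.finite(pixel)) || any(pixel <= 0)) {
    stop("pixel sizes must be positive", call. = FALSE)
  }
  if (any(!is.finite(range)) || any(range <= 0)) {
    stop("scan ranges must be positive", call. = FALSE)
  }
  shape <- as.integer(pmax(1L, round(range / pixel)))
  names(shape) <- .axes
  new("PixelGrid", stage = stage, offset = offset, range = range,
      pixel = pixel, shape = shape)
}

#' Build the PixelGrid described by a parameter tree
#' @param tree a parameter tree carrying stage position, scan offsets
#'   (defaulting to 0), ranges and pixel sizes
#' @return a \linkS4class{PixelGrid}
#' @export
pixelGridFromParameters <- function(tree) {
  gv <- function(group, def = NULL) {
    out <- vapply(.axes, function(a) {
      v <- treeGet(tree, paste(group, a, sep = "/"))
      if (is.null(v)) {
        if (is.null(def)) stop(sprintf("missing parameter '%s/%s'", group, a),
                               call. = FALSE)
        def
      } else as.numeric(v)
    }, numeric(1))
    out
  }
  pixelGrid(stage = gv("stage"), offset = gv("scan/offset", def = 0),
            range = gv("scan/range"), pixel = gv("scan/pixel"))
}

#' AcquisitionTaskGenerator: composable task generation from building blocks
#'
#' Each building block is a function of the loop state returning a list of
#' partial parameter trees (length 0 = veto, 1, or N). Block outputs are
#' broadcast (singletons repeated to the common length N) and deep-merged in
#' block order (later blocks override earlier ones) into complete parameter
#' trees; optional configuration variants then expand each tree into one task
#' holding all variants as separate configurations.
#'
#' @slot targetLevel level the generated tasks are enqueued on
#' @slot blocks ordered list of building-block functions
#' @slot variants named list of partial parameter trees; empty = a single
#'   "main" configuration
#' @slot delay delay (s) attached to the generated tasks
#' @slot name generator name (used in logs/errors)
#' @export
setClass("AcquisitionTaskGenerator",
  representation(targetLevel = "character", blocks = "list",
                 variants = "list", delay = "numeric", name = "character"),
  validity = function(object) {
    if (length(object@blocks) < 1L) return("need at least one building block")
    if (!all(vapply(object@blocks, is.function, logical(1)))) {
      return("blocks must be functions of the loop state")
    }
    if (object@delay < 0) return("delay must be >= 0")
    TRUE
  })

#' Create an AcquisitionTaskGenerator
#' @param targetLevel level name tasks are enqueued on
#' @param blocks ordered list of building-block functions
#'   (\code{function(state) -> list of partial parameter trees})
#' @param variants named list of partial trees; each merged tree is expanded
#'   into one task with one configuration per variant
#' @param delay seconds added to generated tasks' eligibility
#' @param name generator name for logs
#' @return an \linkS4class{AcquisitionTaskGenerator}
#' @export
acquisitionTaskGenerator <- function(targetLevel, blocks, variants = list(),
                                     delay = 0, name = targetLevel) {
  new("AcquisitionTaskGenerator", targetLevel = targetLevel, blocks = blocks,
      variants = variants, delay = as.numeric(delay), name = name)
}

#' StitchResult: an on-the-fly stitched overview canvas
#'
#' @slot canvas fused 2D image (z maximum projection), \code{[y, x]}
#' @slot grid \linkS4class{PixelGrid} of the canvas, in the current tile's
#'   frame
#' @slot shifts named list of integer pixel shifts (dy, dx) applied per tile
#' @slot provenance integer matrix, same shape as canvas: index into
#'   \code{tileIds} of the tile each pixel came from (0 = empty)
#' @slot tileIds measurement ids fused into the canvas (current tile last)
#' @export
setClass("StitchResult",
  representation(canvas = "matrix", grid = "PixelGrid", shifts = "list",
                 provenance = "matrix", tileIds = "character"))

## Mutable runtime objects: S4 handles around an environment slot ------------

#' TaskQueue: the dynamic priority queue of acquisition tasks
#'
#' Tasks are keyed by (level rank, sequence); among tasks whose eligible time
#' has passed, the minimum key is popped next, so pop order is total and
#' deterministic. See \code{\link{taskQueue}}.
#' @slot state internal environment
#' @export
setClass("TaskQueue", representation(state = "environment"))

#' ROIRegistry: bookkeeping of already-imaged regions
#'
#' Append-only registry used to discard re-detections of the same object; a
#' candidate box is discarded iff its IoU with any registered box exceeds the
#' threshold or its center lies inside a registered box.
#' @slot state internal environment
#' @export
setClass("ROIRegistry", representation(state = "environment"))

#' MeasurementStore: persisted measurements with an overlap-queryable index
#' @slot state internal environment
#' @export
setClass("MeasurementStore", representation(state = "environment"))

#' VirtualScene: ground-truth sample for the simulated microscope
#'
#' Holds slide extent, tilt plane, nuclei (ellipsoids with body stain),
#' point emitters (surface pore-like spots, colocalizing two-channel pairs),
#' transient events, the drift model, and the mutable per-spot bleach state.
#' @slot state internal environment
#' @export
setClass("VirtualScene", representation(state = "environment"))

#' SimulatedMicroscope: a microscope interface backed by a VirtualScene
#' @slot state internal environment
#' @export
setClass("SimulatedMicroscope", representation(state = "environment"))
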