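## Building blocks and task generation -----------------------------------------
##
## A building block is a function(state) returning a list of partial parameter
## trees: length 0 vetoes task creation for this invocation, length 1 is
## broadcast against other blocks, length N creates N tasks. Blocks never
## mutate the loop state (detection blocks may update the shared ROI registry,
## which is the registry's job, not the state's).

#' Broadcast and merge building-block outputs
#'
#' Each inner list must have length 0, 1 or N (all lengths > 1 equal). An
#' empty output vetoes the whole invocation. Singletons are repeated to the
#' common length N; element i of the result is the deep merge of every block's
#' i-th (or only) tree, merged in block order so later blocks override earlier
#' ones.
#'
#' @param outputs list of lists of partial parameter trees, one per block
#' @param blockNames optional block names for error messages
#' @return list of N complete(r) parameter trees; empty list if vetoed
#' @export
broadcastCombine <- function(outputs, blockNames = NULL) {
  if (length(outputs) == 0L) return(list())
  lens <- vapply(outputs, length, integer(1))
  if (any(lens == 0L)) return(list())
  big <- unique(lens[lens > 1L])
  if (length(big) > 1L) {
    who <- if (is.null(blockNames)) {
      sprintf("blocks %s", paste(which(lens > 1L), collapse = ", "))
    } else {
      paste(blockNames[lens > 1L], collapse = ", ")
    }
    stop(sprintf("broadcast mismatch: output lengths %s from %s",
                 paste(sort(big), collapse = " vs "), who), call. = FALSE)
  }
  n <- max(lens)
  lapply(seq_len(n), function(i) {
    merged <- emptyParameterTree()
    for (b in seq_along(outputs)) {
      out <- outputs[[b]]
      tree <- if (length(out) == 1L) out[[1L]] else out[[i]]
      merged <- deepMerge(merged, tree)
    }
    merged
  })
}

#' Building block: constant settings loaded from a JSON file
#'
#' The file is read and validated once, when the pipeline is built; a missing
#' or unparseable file therefore fails before the loop starts. Every
#' invocation emits exactly one partial tree equal to the file contents.
#'
#' @param path path to a JSON parameter tree (laser powers, pixel sizes, ...)
#' @return a building-block function
#' @export
settingsFromFile <- function(path) {
  tree <- readParameterTree(path)
  function(state) list(tree)
}

#' Building block: constant settings from an in-memory tree
#' @param tree a parameter tree
#' @return a building-block function
#' @export
settingsBlock <- function(tree) {
  validateParameterTree(tree)
  force(tree)
  function(state) list(tree)
}

#' Building block: iteratively generated stage positions
#'
#' Each invocation emits one tree holding the next stage position. Modes:
#' \describe{
#'   \item{grid}{row-major \code{rows x cols} grid from \code{origin} with
#'     spacing \code{pitch}; vetoes once exhausted.}
#'   \item{spiral}{outward square spiral from \code{origin} with step
#'     \code{pitch} (moves +x, +y once; -x, -y twice; +x, +y three times; ...);
#'     never exhausts.}
#'   \item{list}{emits \code{positions} in order, then vetoes.}
#' }
#' If \code{origin} (or a list position) has a z component, stage z is
#' emitted too; otherwise z is left for another block (e.g. the focus block).
#'
#' @param mode \code{"grid"}, \code{"spiral"} or \code{"list"}
#' @param origin numeric (x, y) or (x, y, z) in um
#' @param pitch spacing in um (> 0; grid and spiral)
#' @param rows,cols grid dimensions
#' @param positions list of numeric (x, y) or (x, y, z) for list mode
#' @return a building-block function
#' @export
positionBlock <- function(mode = c("grid", "spiral", "list"),
                          origin = c(0, 0), pitch = NULL,
                          rows = NULL, cols = NULL, positions = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("grid", "spiral")) {
    if (is.null(pitch) || pitch <= 0) stop("pitch must be > 0", call. = FALSE)
  }
  pos <- switch(mode,
    grid = {
      if (is.null(rows) || is.null(cols)) {
        stop("grid mode needs rows and cols", call. = FALSE)
      }
      grid <- expand.grid(c = seq_len(cols) - 1L, r = seq_len(rows) - 1L)
      lapply(seq_len(nrow(grid)), function(i) {
        c(origin[1] + grid$c[i] * pitch, origin[2] + grid$r[i] * pitch,
          origin[-(1:2)])
      })
    },
    list = {
      if (is.null(positions)) stop("list mode needs positions", call. = FALSE)
      positions
    },
    spiral = NULL)

  env <- new.env(parent = emptyenv())
  env$i <- 0L
  env$at <- c(origin[1], origin[2])      # spiral walker
  env$dir <- 0L                          # 0:+x 1:+y 2:-x 3:-y
  env$runLen <- 1L
  env$leftInRun <- 1L
  env$legsDone <- 0L

  emit <- function(p) {
    tree <- list(stage = list(x = as.numeric(p[1]), y = as.numeric(p[2])))
    if (length(p) >= 3L && !is.na(p[3])) tree$stage$z <- as.numeric(p[3])
    list(tree)
  }

  if (mode == "spiral") {
    zOrigin <- if (length(origin) >= 3L) origin[3] else NA_real_
    steps <- c(1, 0, 0, 1, -1, 0, 0, -1)  # unit moves per direction
    dim(steps) <- c(2, 4)
    function(state) {
      env$i <- env$i + 1L
      if (env$i == 1L) return(emit(c(origin[1], origin[2], zOrigin)))
      env$at <- env$at + steps[, env$dir + 1L] * pitch
      env$leftInRun <- env$leftInRun - 1L
      if (env$leftInRun == 0L) {
        env$dir <- (env$dir + 1L) %% 4L
        env$legsDone <- env$legsDone + 1L
        if (env$legsDone %% 2L == 0L) env$runLen <- env$runLen + 1L
        env$leftInRun <- env$runLen
      }
      emit(c(env$at, zOrigin))
    }
  } else {
    function(state) {
      env$i <- env$i + 1L
      if (env$i > length(pos)) return(list())  # exhausted -> veto
      emit(pos[[env$i]])
    }
  }
}

#' Building block: inherit the triggering measurement's stage position
#'
#' Detail tasks are scanned from the same stage position as their parent
#' overview; the ROI is expressed through scan offsets by a detection block.
#'
#' @return a building-block function
#' @export
stagePositionBlock <- function() {
  function(state) {
    meas <- lastMeasurement(state)
    if (is.null(meas)) return(list())
    p <- parameters(configurations(meas)[[1]])
    list(list(stage = list(x = treeGet(p, "stage/x"),
                           y = treeGet(p, "stage/y"),
                           z = treeGet(p, "stage/z"))))
  }
}

#' Building block: image-based focus update
#'
#' Computes a z correction from the triggering measurement's z-stack (see
#' \code{\link{focusUpdate}}) and emits the corrected absolute stage z, so no
#' dedicated focus-search images are needed. Combine with a position block
#' that emits only x and y.
#'
#' @param channel detection channel used for the focus metric
#' @param maxStep clamp for a single correction (um)
#' @param minContrast minimum metric peak-to-mean ratio; below it the
#'   correction is 0 (low confidence)
#' @return a building-block function
#' @export
focusBlock <- function(channel = 1L, maxStep = 1, minContrast = 1.05) {
  function(state) {
    meas <- lastMeasurement(state)
    if (is.null(meas)) return(list())
    p <- parameters(configurations(meas)[[1]])
    stack <- stacks(meas)[[1]][channel, , , , drop = TRUE]
    if (length(dim(stack)) != 3L) {
      dim(stack) <- c(1L, dim(stack))  # single plane: no update possible
    }
    dz <- treeGet(p, "scan/pixel/z")
    upd <- if (dim(stack)[1] >= 3L) {
      focusUpdate(stack, dz = dz, maxStep = maxStep,
                  minContrast = minContrast)
    } else {
      list(dz = 0, confident = FALSE)
    }
    z0 <- treeGet(p, "stage/z")
    list(list(stage = list(z = z0 + upd$dz)))
  }
}

#' Building block: detect objects and emit scan windows for them
#'
#' Composes a data selector (which image to analyse: the last measurement or
#' an on-the-fly stitched canvas), a detector returning physical bounding
#' boxes, and the pixel-to-stage translation into scan offsets/ranges. Boxes
#' already imaged (per the shared ROI registry) and boxes outside the scanner
#' limits are skipped.
#'
#' @param detector \code{function(image, grid, state) -> list of}
#'   \linkS4class{PhysicalBox}
#' @param selector \code{function(state) -> list(image, grid)}; default:
#'   z-maximum projection of channel 1 of the triggering measurement
#' @param registry optional \linkS4class{ROIRegistry}; when NULL the loop
#'   state's registry is used if present
#' @param limits scanner half-ranges (um)
#' @param minFov minimum detail field of view per axis (um)
#' @param level level name used for the consecutive-empty-FOV counter
#' @return a building-block function emitting one partial tree (scan
#'   offsets/ranges) per kept detection
#' @export
detectionBlock <- function(detector, selector = lastImageSelector(),
                           registry = NULL, limits = 40, minFov = 1,
                           level = NULL) {
  function(state) {
    sel <- selector(state)
    if (is.null(sel)) return(list())
    boxes <- detector(sel$image, sel$grid, state)
    meas <- lastMeasurement(state)
    lvl <- level %||% levelId(meas)
    noteDetections(state, lvl, length(boxes))
    reg <- registry %||% state$registry
    p <- parameters(configurations(meas)[[1]])
    stage <- c(x = treeGet(p, "stage/x"), y = treeGet(p, "stage/y"),
               z = treeGet(p, "stage/z"))
    out <- list()
    for (box in boxes) {
      if (!is.null(reg) &&
          registryCheckAdd(reg, box, id = measurementId(meas)) == "discarded") {
        next
      }
      tree <- physicalToScan(box, stage, limits = limits, minFov = minFov)
      if (is.null(tree)) next  # outside scanner limits: skip, don't die
      out[[length(out) + 1L]] <- tree
    }
    out
  }
}

#' Data selectors for detection blocks
#'
#' \code{lastImageSelector} returns the z-maximum projection of one channel of
#' the triggering measurement together with its pixel grid.
#' \code{stitchedSelector} instead stitches the triggering overview with all
#' previously acquired overlapping tiles of the same level
#' (\code{\link{stitchNeighbors}}) so objects straddling tile borders become
#' detectable.
#'
#' @param channel detection channel
#' @param store a \linkS4class{MeasurementStore} (stitched selector)
#' @param register apply phase-correlation registration to neighbours
#' @return a selector function \code{function(state) -> list(image, grid)}
#' @export
lastImageSelector <- function(channel = 1L) {
  function(state) {
    meas <- lastMeasurement(state)
    if (is.null(meas)) return(NULL)
    stack <- stacks(meas)[[1]]
    img <- apply(stack[channel, , , , drop = FALSE], c(3, 4), max)
    ## z is collapsed by the projection: hand out a grid whose single z pixel
    ## spans the full z range, so detected boxes inherit the overview's depth
    list(image = img, grid = .flatGrid(measurementGrid(meas)))
  }
}

#' @rdname lastImageSelector
#' @export
stitchedSelector <- function(store, channel = 1L, register = TRUE) {
  function(state) {
    meas <- lastMeasurement(state)
    if (is.null(meas)) return(NULL)
    res <- stitchNeighbors(meas, store, register = register,
                           channel = channel)
    list(image = res@canvas, grid = res@grid, stitch = res)
  }
}

#' Build tasks from a generator's blocks
#'
#' Runs every block on the loop state, broadcasts and merges their outputs,
#' expands configuration variants, and returns fully validated tasks carrying
#' the generator's delay and the triggering measurement's id as parent. Used
#' internally by \code{\link{runLoop}} for generator callbacks; exposed for
#' testing and custom loops.
#'
#' @param generator an \linkS4class{AcquisitionTaskGenerator}
#' @param state the loop state
#' @return list of \linkS4class{AcquisitionTask} (possibly empty)
#' @export
buildTasks <- function(generator, state) {
  outputs <- lapply(generator@blocks, function(b) b(state))
  blockNames <- names(generator@blocks) %||% NULL
  merged <- broadcastCombine(outputs, blockNames)
  if (length(merged) == 0L) return(list())
  parent <- if (!is.null(state$current)) measurementId(state$current)
            else NA_character_
  lapply(merged, function(tree) {
    confs <- if (length(generator@variants) == 0L) {
      list(configuration("main", tree))
    } else {
      vnames <- names(generator@variants)
      if (is.null(vnames) || any(!nzchar(vnames))) {
        stop("configuration variants must be named", call. = FALSE)
      }
      lapply(vnames, function(v) {
        configuration(v, deepMerge(tree, generator@variants[[v]]))
      })
    }
    task <- acquisitionTask(generator@targetLevel, confs,
                            delay = generator@delay, parentId = parent)
    validateTask(task, state$levels)
  })
}
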