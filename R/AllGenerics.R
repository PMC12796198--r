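## Generics, accessors and show methods ---------------------------------------

#' Microscope interface generics
#'
#' Any microscope backend (live adapter or simulator) implements these four
#' generics: \code{applyParameters} sets the measurement parameters,
#' \code{acquireFrame} acquires with the most recently applied parameters and
#' returns a \code{[channel, z, y, x]} array, \code{clockTime} returns the
#' backend's non-decreasing clock (seconds), and \code{waitUntil} advances /
#' sleeps until a clock time (used for delayed tasks).
#'
#' @param microscope a microscope backend
#' @param parameters a parameter tree
#' @param time target clock time (s)
#' @return \code{applyParameters}/\code{waitUntil}: the microscope, invisibly;
#'   \code{acquireFrame}: a 4D array; \code{clockTime}: a number.
#' @name microscope-interface
NULL

#' @rdname microscope-interface
#' @export
setGeneric("applyParameters", function(microscope, parameters)
  standardGeneric("applyParameters"))

#' @rdname microscope-interface
#' @export
setGeneric("acquireFrame", function(microscope)
  standardGeneric("acquireFrame"))

#' @rdname microscope-interface
#' @export
setGeneric("clockTime", function(microscope) standardGeneric("clockTime"))

#' @rdname microscope-interface
#' @export
setGeneric("waitUntil", function(microscope, time)
  standardGeneric("waitUntil"))

## --- small accessors --------------------------------------------------------

#' Accessors for tasks, measurements, boxes and grids
#'
#' @param x the object
#' @param ... unused
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("levelId", function(x) standardGeneric("levelId"))
#' @rdname accessors
#' @export
setGeneric("taskSequence", function(x) standardGeneric("taskSequence"))
#' @rdname accessors
#' @export
setGeneric("configurations", function(x) standardGeneric("configurations"))
#' @rdname accessors
#' @export
setGeneric("taskDelay", function(x) standardGeneric("taskDelay"))
#' @rdname accessors
#' @export
setGeneric("eligibleTime", function(x) standardGeneric("eligibleTime"))
#' @rdname accessors
#' @export
setGeneric("parentId", function(x) standardGeneric("parentId"))
#' @rdname accessors
#' @export
setGeneric("measurementId", function(x) standardGeneric("measurementId"))
#' @rdname accessors
#' @export
setGeneric("stacks", function(x) standardGeneric("stacks"))
#' @rdname accessors
#' @export
setGeneric("acquiredAt", function(x) standardGeneric("acquiredAt"))
#' @rdname accessors
#' @export
setGeneric("parameters", function(x) standardGeneric("parameters"))
#' @rdname accessors
#' @export
setGeneric("configurationName", function(x) standardGeneric("configurationName"))
#' @rdname accessors
#' @export
setGeneric("boxCenter", function(x) standardGeneric("boxCenter"))
#' @rdname accessors
#' @export
setGeneric("boxExtent", function(x) standardGeneric("boxExtent"))

setMethod("levelId", "AcquisitionTask", function(x) x@levelId)
setMethod("levelId", "Measurement", function(x) x@levelId)
setMethod("taskSequence", "AcquisitionTask", function(x) x@sequence)
setMethod("taskSequence", "Measurement", function(x) x@sequence)
setMethod("configurations", "AcquisitionTask", function(x) x@configurations)
setMethod("configurations", "Measurement", function(x) x@configurations)
setMethod("taskDelay", "AcquisitionTask", function(x) x@delay)
setMethod("eligibleTime", "AcquisitionTask", function(x) x@eligibleTime)
setMethod("parentId", "AcquisitionTask", function(x) x@parentId)
setMethod("parentId", "Measurement", function(x) x@parentId)
setMethod("measurementId", "Measurement", function(x) x@id)
setMethod("stacks", "Measurement", function(x) x@stacks)
setMethod("acquiredAt", "Measurement", function(x) x@acquiredAt)
setMethod("parameters", "Configuration", function(x) x@parameters)
setMethod("configurationName", "Configuration", function(x) x@name)
setMethod("boxCenter", "PhysicalBox",
          function(x) (x@minCorner + x@maxCorner) / 2)
setMethod("boxExtent", "PhysicalBox",
          function(x) x@maxCorner - x@minCorner)

#' Pixel grid of one configuration of a measurement
#' @param measurement a \linkS4class{Measurement}
#' @param config configuration index
#' @return a \linkS4class{PixelGrid}
#' @export
measurementGrid <- function(measurement, config = 1L) {
  pixelGridFromParameters(parameters(configurations(measurement)[[config]]))
}

## --- show methods -----------------------------------------------------------

setMethod("show", "AcquisitionTask", function(object) {
  cat(sprintf("AcquisitionTask on level '%s' (%d configuration%s, delay %gs%s)\n",
              object@levelId, length(object@configurations),
              if (length(object@configurations) == 1L) "" else "s",
              object@delay,
              if (is.na(object@sequence)) ", not enqueued"
              else sprintf(", seq %d", object@sequence)))
})

setMethod("show", "Measurement", function(object) {
  d <- dim(object@stacks[[1]])
  cat(sprintf("Measurement %s  level '%s'  seq %d  clock %.2fs\n",
              object@id, object@levelId, object@sequence, object@acquiredAt))
  cat(sprintf("  %d configuration(s); stack 1: %d channel(s), %d x %d x %d (z,y,x)\n",
              length(object@configurations), d[1], d[2], d[3], d[4]))
})

setMethod("show", "PhysicalBox", function(object) {
  cat(sprintf("PhysicalBox [%.3f..%.3f] x [%.3f..%.3f] x [%.3f..%.3f] um\n",
              object@minCorner["x"], object@maxCorner["x"],
              object@minCorner["y"], object@maxCorner["y"],
              object@minCorner["z"], object@maxCorner["z"]))
})

setMethod("show", "PixelGrid", function(object) {
  cat(sprintf("PixelGrid %d x %d x %d (x,y,z) px, pixel (%g, %g, %g) um, center (%g, %g, %g)\n",
              object@shape["x"], object@shape["y"], object@shape["z"],
              object@pixel["x"], object@pixel["y"], object@pixel["z"],
              object@stage["x"] + object@offset["x"],
              object@stage["y"] + object@offset["y"],
              object@stage["z"] + object@offset["z"]))
})

setMethod("show", "TaskQueue", function(object) {
  cat(sprintf("TaskQueue with %d pending task(s)\n", queueSize(object)))
})

setMethod("show", "AcquisitionTaskGenerator", function(object) {
  cat(sprintf("AcquisitionTaskGenerator '%s' -> level '%s' (%d block(s)%s)\n",
              object@name, object@targetLevel, length(object@blocks),
              if (length(object@variants))
                sprintf(", %d variant(s)", length(object@variants)) else ""))
})

setMethod("show", "StitchResult", function(object) {
  cat(sprintf("StitchResult: %d x %d canvas from %d tile(s)\n",
              nrow(object@canvas), ncol(object@canvas),
              length(object@tileIds)))
})

setMethod("show", "VirtualScene", function(object) {
  s <- object@state
  cat(sprintf("VirtualScene: %d nuclei, %d spot(s), extent %g x %g um, seed %d\n",
              length(s$nuclei), nrow(s$spots), s$extent[1], s$extent[2],
              s$seed))
})

setMethod("show", "SimulatedMicroscope", function(object) {
  cat(sprintf("SimulatedMicroscope at clock %.2fs\n", object@state$t))
})

setMethod("show", "MeasurementStore", function(object) {
  cat(sprintf("MeasurementStore with %d measurement(s)%s\n",
              storeCount(object),
              if (is.null(object@state$root)) " (in-memory)"
              else sprintf(" at %s", object@state$root)))
})

setMethod("show", "ROIRegistry", function(object) {
  cat(sprintf("ROIRegistry with %d box(es), IoU threshold %.2f\n",
              length(object@state$boxes), object@state$iouThreshold))
})
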