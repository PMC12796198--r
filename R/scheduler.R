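## The main acquisition loop ---------------------------------------------------

#' Create a stopping criterion
#'
#' Stopping criteria are pure predicates over the loop state, evaluated after
#' each acquisition's callbacks have run.
#'
#' @param kind one of \code{"max_images"}, \code{"max_time"}, \code{"custom"}
#' @param n for \code{max_images}: stop once this many measurements have been
#'   acquired (>= 1)
#' @param t for \code{max_time}: stop once \code{clock - start >= t} seconds
#'   (> 0)
#' @param predicate for \code{custom}: \code{function(state) -> logical}
#' @param reason human-readable stop reason recorded in the log
#' @return a \code{StoppingCriterion} (list with \code{fire} and
#'   \code{reason})
#' @export
makeStoppingCriterion <- function(kind = c("max_images", "max_time", "custom"),
                                  n = NULL, t = NULL, predicate = NULL,
                                  reason = NULL) {
  kind <- match.arg(kind)
  crit <- switch(kind,
    max_images = {
      if (is.null(n) || n < 1) {
        stop("max_images needs n >= 1", call. = FALSE)
      }
      list(fire = function(state) state$images >= n,
           reason = reason %||% sprintf("max-images:%d", n))
    },
    max_time = {
      if (is.null(t) || t <= 0) stop("max_time needs t > 0", call. = FALSE)
      list(fire = function(state) state$clock() - state$startClock >= t,
           reason = reason %||% sprintf("max-time:%gs", t))
    },
    custom = {
      if (!is.function(predicate)) {
        stop("custom criterion needs a predicate function", call. = FALSE)
      }
      list(fire = predicate, reason = reason %||% "custom")
    })
  class(crit) <- "StoppingCriterion"
  crit
}

#' Stop when no objects have been found for k consecutive fields of view
#'
#' Convenience wrapper around a custom criterion: building blocks report
#' detections via \code{\link{noteDetections}}; this criterion fires when the
#' counter of consecutive object-free acquisitions on \code{level} reaches
#' \code{k}.
#'
#' @param k number of consecutive empty fields of view
#' @param level level name the counter applies to
#' @return a \code{StoppingCriterion}
#' @export
stopWhenNothingFound <- function(k, level) {
  makeStoppingCriterion("custom",
    predicate = function(state) {
      cnt <- state$emptyStreak[[level]] %||% 0L
      cnt >= k
    },
    reason = sprintf("no-objects:%d-consecutive-%s", k, level))
}

#' Record the number of objects a detection block found
#'
#' Maintains the per-level consecutive-empty counter used by
#' \code{\link{stopWhenNothingFound}}. Multiple detection blocks reporting on
#' the same measurement count as one field of view: the counter advances at
#' most once per measurement and any positive report resets it.
#'
#' @param state the loop state
#' @param level level name of the triggering measurement
#' @param n number of objects detected
#' @return invisibly, the updated streak length
#' @export
noteDetections <- function(state, level, n) {
  id <- if (!is.null(state$current)) measurementId(state$current)
        else NA_character_
  cur <- state$emptyStreak[[level]] %||% 0L
  seen <- state$emptyStreakId[[level]] %||% ""
  if (!is.na(id) && identical(seen, id)) {
    if (n > 0) state$emptyStreak[[level]] <- 0L
  } else {
    state$emptyStreak[[level]] <- if (n > 0) 0L else cur + 1L
    state$emptyStreakId[[level]] <- id
  }
  invisible(state$emptyStreak[[level]])
}

#' Most recent measurement seen by the loop
#'
#' @param state the loop state
#' @param level optional level name; default: the measurement that triggered
#'   the currently running callbacks
#' @return a \linkS4class{Measurement} or \code{NULL}
#' @export
lastMeasurement <- function(state, level = NULL) {
  if (is.null(level)) state$current else state$lastByLevel[[level]]
}

.newLoopState <- function(queue, levels, microscope, store, registry) {
  state <- new.env(parent = emptyenv())
  state$queue <- queue
  state$levels <- levels
  names(state$levels) <- vapply(levels, function(l) l@name, character(1))
  state$microscope <- microscope
  state$store <- store
  state$registry <- registry
  state$images <- 0L
  state$startClock <- clockTime(microscope)
  state$lastByLevel <- list()
  state$current <- NULL
  state$emptyStreak <- list()
  state$log <- list()
  state$clock <- function() clockTime(microscope)
  state
}

.logEvent <- function(state, event, ...) {
  rec <- c(list(event = event, clock = round(clockTime(state$microscope), 6)),
           list(...))
  state$log[[length(state$log) + 1L]] <- rec
  invisible(rec)
}

.acquireTask <- function(microscope, task) {
  stacks <- vector("list", length(task@configurations))
  for (i in seq_along(task@configurations)) {
    applyParameters(microscope, task@configurations[[i]]@parameters)
    stacks[[i]] <- acquireFrame(microscope)
  }
  new("Measurement",
      id = sprintf("m%06d", task@sequence),
      levelId = task@levelId,
      sequence = task@sequence,
      configurations = task@configurations,
      stacks = stacks,
      acquiredAt = clockTime(microscope),
      parentId = task@parentId)
}

.invokeCallback <- function(cb, state) {
  if (is(cb, "AcquisitionTaskGenerator")) {
    tasks <- buildTasks(cb, state)
  } else {
    tasks <- cb(state)
  }
  if (is(tasks, "AcquisitionTask")) tasks <- list(tasks)
  if (is.list(tasks)) {
    for (task in tasks) {
      if (is(task, "AcquisitionTask")) {
        enqueueTask(state$queue, task, clock = state$clock())
      }
    }
  }
  invisible(NULL)
}

#' Run the main acquisition loop
#'
#' Repeats: pop the highest-priority eligible task, apply each configuration's
#' parameters and acquire, persist the measurement, run the level's callbacks
#' in registration order, then evaluate the stopping criteria. When only
#' future-eligible (delayed) tasks remain, the clock advances to the earliest
#' eligible time. The loop terminates when the queue is empty or a stopping
#' criterion fires.
#'
#' Acquisition failures and callback exceptions are logged and the loop
#' continues (set \code{abortOnError} to stop instead), so a misbehaving
#' detector cannot kill an unattended overnight run.
#'
#' @param queue a \linkS4class{TaskQueue} seeded with at least one task
#' @param levels list of \linkS4class{HierarchyLevel} (the same registry the
#'   queue was built with)
#' @param microscope a microscope backend (see
#'   \code{\link{simulatedMicroscope}})
#' @param stops list of stopping criteria from
#'   \code{\link{makeStoppingCriterion}}
#' @param store optional \linkS4class{MeasurementStore}; measurements are
#'   persisted before callbacks run
#' @param registry optional \linkS4class{ROIRegistry} shared with detection
#'   blocks
#' @param logPath optional path; the experiment log is written there as JSONL
#' @param abortOnError abort the run on acquisition/callback errors
#' @return an \code{ExperimentLog}: list with \code{records} (one per
#'   acquisition/stop event), \code{stopReason} and \code{imagesAcquired}
#' @export
runLoop <- function(queue, levels, microscope, stops = list(), store = NULL,
                    registry = NULL, logPath = NULL, abortOnError = FALSE) {
  if (is(stops, "StoppingCriterion")) stops <- list(stops)
  state <- .newLoopState(queue, levels, microscope, store, registry)
  stopReason <- NULL

  while (is.null(stopReason)) {
    if (queueSize(queue) == 0L) {
      stopReason <- "queue-empty"
      break
    }
    task <- popTask(queue, clock = state$clock())
    if (is.null(task)) {
      waitUntil(microscope, nextEligibleTime(queue))
      next
    }

    meas <- tryCatch(.acquireTask(microscope, task), error = function(e) e)
    if (inherits(meas, "error")) {
      .logEvent(state, "acquisition-failed", level = task@levelId,
                sequence = task@sequence,
                outcome = conditionMessage(meas))
      if (abortOnError) {
        stopReason <- "acquisition-error"
        break
      }
      next
    }

    if (!is.null(store)) saveMeasurement(store, meas)
    state$images <- state$images + 1L
    state$lastByLevel[[meas@levelId]] <- meas
    state$current <- meas
    st <- treeGet(meas@configurations[[1]]@parameters, "stage/x")
    .logEvent(state, "acquisition", id = meas@id, level = meas@levelId,
              sequence = meas@sequence,
              stage = list(
                x = treeGet(meas@configurations[[1]]@parameters, "stage/x"),
                y = treeGet(meas@configurations[[1]]@parameters, "stage/y"),
                z = treeGet(meas@configurations[[1]]@parameters, "stage/z")),
              outcome = "ok")

    lvl <- state$levels[[meas@levelId]]
    for (cb in lvl@callbacks) {
      res <- tryCatch(.invokeCallback(cb, state), error = function(e) e)
      if (inherits(res, "error")) {
        .logEvent(state, "callback-failed", level = meas@levelId,
                  sequence = meas@sequence,
                  outcome = conditionMessage(res))
        if (abortOnError) {
          stopReason <- "callback-error"
          break
        }
      }
    }
    if (!is.null(stopReason)) break

    for (crit in stops) {
      if (isTRUE(crit$fire(state))) {
        stopReason <- crit$reason
        break
      }
    }
  }

  .logEvent(state, "stop", outcome = stopReason)
  log <- structure(list(records = state$log, stopReason = stopReason,
                        imagesAcquired = state$images,
                        finalClock = clockTime(microscope)),
                   class = "ExperimentLog")
  if (!is.null(logPath)) writeExperimentLog(log, logPath)
  log
}

#' Write an experiment log as JSON lines
#'
#' One JSON object per acquisition/callback/stop event; a greppable audit
#' trail for long unattended runs.
#'
#' @param log an \code{ExperimentLog} from \code{\link{runLoop}}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeExperimentLog <- function(log, path) {
  lines <- vapply(log$records, function(rec) {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.ExperimentLog <- function(x, ...) {
  cat(sprintf("ExperimentLog: %d acquisition(s), stopped for '%s' at clock %.2fs\n",
              x$imagesAcquired, x$stopReason, x$finalClock))
  invisible(x)
}

#' Tabulate acquisitions in an experiment log
#'
#' @param log an \code{ExperimentLog}
#' @return data.frame with one row per acquisition: id, level, sequence,
#'   clock, stage x/y/z
#' @export
logAcquisitions <- function(log) {
  acq <- Filter(function(r) identical(r$event, "acquisition"), log$records)
  if (length(acq) == 0L) {
    return(data.frame(id = character(0), level = character(0),
                      sequence = integer(0), clock = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  data.frame(
    id = vapply(acq, function(r) r$id, character(1)),
    level = vapply(acq, function(r) r$level, character(1)),
    sequence = vapply(acq, function(r) as.integer(r$sequence), integer(1)),
    clock = vapply(acq, function(r) as.numeric(r$clock), numeric(1)),
    x = vapply(acq, function(r) as.numeric(r$stage$x), numeric(1)),
    y = vapply(acq, function(r) as.numeric(r$stage$y), numeric(1)),
    z = vapply(acq, function(r) as.numeric(r$stage$z), numeric(1)),
    stringsAsFactors = FALSE)
}
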