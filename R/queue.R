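## Task validation and the priority queue -------------------------------------

#' Validate an acquisition task against a level registry
#'
#' A task is valid iff every configuration carries a stage position, scan
#' ranges and pixel sizes (see \code{requiredTaskPaths}), its delay is
#' non-negative, and its level is registered.
#'
#' @param task an \linkS4class{AcquisitionTask}
#' @param levels list of registered \linkS4class{HierarchyLevel} objects
#' @return the task, unchanged, if valid; otherwise an error naming the
#'   offending path or level
#' @export
validateTask <- function(task, levels) {
  stopifnot(is(task, "AcquisitionTask"))
  levelNames <- vapply(levels, function(l) l@name, character(1))
  if (!task@levelId %in% levelNames) {
    stop(sprintf("unknown hierarchy level '%s'", task@levelId), call. = FALSE)
  }
  if (task@delay < 0) stop("task delay must be >= 0", call. = FALSE)
  for (cf in task@configurations) {
    for (p in requiredTaskPaths()) {
      if (is.null(treeGet(cf@parameters, p))) {
        stop(sprintf("configuration '%s' is missing required parameter '%s'",
                     cf@name, p), call. = FALSE)
      }
    }
    validateParameterTree(cf@parameters)
  }
  task
}

#' Create a task queue
#'
#' The queue owns the experiment-wide sequence counter: sequence numbers are
#' assigned at enqueue time and are strictly increasing. Pop order is
#' ascending (level rank, sequence) among tasks whose eligible time has
#' passed, i.e. details (lower rank) preempt overviews, FIFO within a level.
#'
#' @param levels list of \linkS4class{HierarchyLevel} objects; ranks must be
#'   unique
#' @return a \linkS4class{TaskQueue}
#' @export
taskQueue <- function(levels) {
  ranks <- vapply(levels, function(l) l@rank, integer(1))
  names(ranks) <- vapply(levels, function(l) l@name, character(1))
  if (anyDuplicated(ranks)) stop("level ranks must be unique", call. = FALSE)
  if (anyDuplicated(names(ranks))) {
    stop("level names must be unique", call. = FALSE)
  }
  state <- new.env(parent = emptyenv())
  state$tasks <- list()
  state$counter <- 0L
  state$ranks <- ranks
  state$levels <- levels
  new("TaskQueue", state = state)
}

#' Enqueue a task
#'
#' Validates the task, assigns the next sequence number and computes its
#' eligible time as \code{clock + delay}.
#'
#' @param queue a \linkS4class{TaskQueue}
#' @param task an \linkS4class{AcquisitionTask}
#' @param clock current clock time (s)
#' @return the enqueued task (with sequence and eligible time), invisibly
#' @export
enqueueTask <- function(queue, task, clock = 0) {
  s <- queue@state
  task <- validateTask(task, s$levels)
  s$counter <- s$counter + 1L
  task@sequence <- s$counter
  task@eligibleTime <- clock + task@delay
  s$tasks[[length(s$tasks) + 1L]] <- task
  invisible(task)
}

#' Pop the highest-priority eligible task
#'
#' @param queue a \linkS4class{TaskQueue}
#' @param clock current clock time (s); tasks with a future eligible time are
#'   never popped
#' @return the popped \linkS4class{AcquisitionTask}, or \code{NULL} when no
#'   task is eligible
#' @export
popTask <- function(queue, clock = Inf) {
  s <- queue@state
  if (length(s$tasks) == 0L) return(NULL)
  elig <- vapply(s$tasks, function(t) t@eligibleTime <= clock, logical(1))
  if (!any(elig)) return(NULL)
  idx <- which(elig)
  ranks <- vapply(s$tasks[idx], function(t) s$ranks[[t@levelId]], integer(1))
  seqs <- vapply(s$tasks[idx], function(t) t@sequence, integer(1))
  best <- idx[order(ranks, seqs)[1L]]
  task <- s$tasks[[best]]
  s$tasks[[best]] <- NULL
  task
}

#' Number of pending tasks
#' @param queue a \linkS4class{TaskQueue}
#' @return integer count
#' @export
queueSize <- function(queue) length(queue@state$tasks)

#' Earliest eligible time among pending tasks
#' @param queue a \linkS4class{TaskQueue}
#' @return clock seconds, or \code{Inf} for an empty queue
#' @export
nextEligibleTime <- function(queue) {
  s <- queue@state
  if (length(s$tasks) == 0L) return(Inf)
  min(vapply(s$tasks, function(t) t@eligibleTime, numeric(1)))
}

#' All pending tasks (inspection helper)
#' @param queue a \linkS4class{TaskQueue}
#' @return list of \linkS4class{AcquisitionTask}
#' @export
pendingTasks <- function(queue) queue@state$tasks

#' Rank of a registered level
#' @param queue a \linkS4class{TaskQueue}
#' @param levelId level name
#' @return integer rank
#' @export
levelRank <- function(queue, levelId) queue@state$ranks[[levelId]]
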