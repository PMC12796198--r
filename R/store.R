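## Measurement persistence -------------------------------------------------------
##
## Measurements are kept in an in-memory index (fast overlap queries for
## stitching) and, when a root directory is set, persisted as one 16-bit
## multi-page TIFF per configuration (page order: channel-major, then z) plus
## one JSON sidecar per measurement holding the full parameter trees, level,
## parent, sequence and clock -- everything a proprietary container would.

#' Create a measurement store
#' @param root optional directory; when given, every saved measurement is
#'   written to disk (TIFF + JSON sidecar)
#' @return a \linkS4class{MeasurementStore}
#' @export
measurementStore <- function(root = NULL) {
  st <- new.env(parent = emptyenv())
  st$items <- list()
  st$root <- root
  if (!is.null(root) && !dir.exists(root)) {
    dir.create(root, recursive = TRUE)
  }
  new("MeasurementStore", state = st)
}

.measurementBaseName <- function(measurement, configName = NULL) {
  base <- sprintf("%06d_%s", taskSequence(measurement), levelId(measurement))
  if (is.null(configName)) base else sprintf("%s_%s", base, configName)
}

#' Persist a measurement
#'
#' @param store a \linkS4class{MeasurementStore}
#' @param measurement a \linkS4class{Measurement}
#' @return the measurement id, invisibly
#' @export
saveMeasurement <- function(store, measurement) {
  st <- store@state
  id <- measurementId(measurement)
  if (!is.null(st$items[[id]])) {
    stop(sprintf("measurement id '%s' already stored (sequence collision)",
                 id), call. = FALSE)
  }
  box <- gridBox(measurementGrid(measurement))
  st$items[[id]] <- list(id = id, measurement = measurement, box = box,
                         level = levelId(measurement),
                         sequence = taskSequence(measurement),
                         clock = acquiredAt(measurement))
  if (!is.null(st$root)) .writeMeasurementFiles(st$root, measurement)
  invisible(id)
}

.writeMeasurementFiles <- function(root, measurement) {
  confs <- configurations(measurement)
  for (i in seq_along(confs)) {
    stack <- stacks(measurement)[[i]]
    d <- dim(stack)  # [ch, z, y, x]
    pages <- list()
    for (ch in seq_len(d[1])) for (k in seq_len(d[2])) {
      pages[[length(pages) + 1L]] <- stack[ch, k, , ] / 65535
    }
    tiff::writeTIFF(pages,
                    file.path(root, paste0(.measurementBaseName(
                      measurement, configurationName(confs[[i]])), ".tiff")),
                    bits.per.sample = 16L)
  }
  sidecar <- list(
    id = measurementId(measurement),
    level = levelId(measurement),
    sequence = taskSequence(measurement),
    parent = parentId(measurement),
    clock = acquiredAt(measurement),
    configurations = lapply(seq_along(confs), function(i) {
      list(name = configurationName(confs[[i]]),
           parameters = .sortTree(parameters(confs[[i]])),
           stackDim = dim(stacks(measurement)[[i]]))
    }))
  writeLines(as.character(jsonlite::toJSON(sidecar, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             file.path(root, paste0(.measurementBaseName(measurement),
                                    ".json")))
  invisible(NULL)
}

#' Reload a measurement from its TIFF + sidecar files
#'
#' Lossless round-trip of \code{\link{saveMeasurement}} for integer count
#' data in [0, 65535].
#'
#' @param root store directory
#' @param sequence the measurement's sequence number
#' @param level the measurement's level name
#' @return a \linkS4class{Measurement}
#' @export
readMeasurementFiles <- function(root, sequence, level) {
  base <- sprintf("%06d_%s", sequence, level)
  sidecar <- jsonlite::fromJSON(file.path(root, paste0(base, ".json")),
                                simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  confs <- list(); stks <- list()
  for (cf in sidecar$configurations) {
    pages <- tiff::readTIFF(file.path(root, paste0(base, "_", cf$name,
                                                   ".tiff")),
                            all = TRUE)
    d <- as.integer(unlist(cf$stackDim))
    stack <- array(0, d)
    p <- 0L
    for (ch in seq_len(d[1])) for (k in seq_len(d[2])) {
      p <- p + 1L
      stack[ch, k, , ] <- round(pages[[p]] * 65535)
    }
    confs[[length(confs) + 1L]] <-
      configuration(cf$name, .normalizeTree(cf$parameters))
    stks[[length(stks) + 1L]] <- stack
  }
  new("Measurement", id = sidecar$id, levelId = sidecar$level,
      sequence = as.integer(sidecar$sequence), configurations = confs,
      stacks = stks, acquiredAt = as.numeric(sidecar$clock),
      parentId = sidecar$parent %||% NA_character_)
}

#' Number of stored measurements
#' @param store a \linkS4class{MeasurementStore}
#' @return integer
#' @export
storeCount <- function(store) length(store@state$items)

#' Ids of stored measurements (in storage order)
#' @param store a \linkS4class{MeasurementStore}
#' @return character vector
#' @export
storedIds <- function(store) names(store@state$items)

#' Retrieve a stored measurement by id
#' @param store a \linkS4class{MeasurementStore}
#' @param id measurement id
#' @return a \linkS4class{Measurement}
#' @export
loadMeasurement <- function(store, id) {
  item <- store@state$items[[id]]
  if (is.null(item)) stop(sprintf("no measurement '%s' in store", id),
                          call. = FALSE)
  item$measurement
}

#' Query stored measurements by level and physical overlap
#'
#' @param store a \linkS4class{MeasurementStore}
#' @param level level name to restrict to (NULL = all levels)
#' @param box a \linkS4class{PhysicalBox} the tiles must intersect
#' @param axes axes on which intersection is required (default all three;
#'   use \code{c("x", "y")} for lateral tile neighbourhoods)
#' @return list of index entries: \code{id}, \code{measurement}, \code{box},
#'   \code{level}, \code{sequence}, \code{clock}
#' @export
queryOverlap <- function(store, level = NULL, box, axes = c("x", "y", "z")) {
  Filter(function(item) {
    if (!is.null(level) && item$level != level) return(FALSE)
    all(vapply(axes, function(a) {
      item$box@minCorner[[a]] < box@maxCorner[[a]] &&
        item$box@maxCorner[[a]] > box@minCorner[[a]]
    }, logical(1)))
  }, store@state$items)
}

#' Per-level acquisition counts of a store
#' @param store a \linkS4class{MeasurementStore}
#' @return named integer vector
#' @export
storeLevelCounts <- function(store) {
  lv <- vapply(store@state$items, function(i) i$level, character(1))
  if (length(lv) == 0L) return(integer(0))
  table(lv) |> c()
}
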