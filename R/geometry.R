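## Coordinate frames and ROI bookkeeping ---------------------------------------

#' Convert pixel indices to stage coordinates
#'
#' Pixel indices are 0-based and may be fractional (sub-pixel centres). Per
#' axis, \code{phys = stage + offset - range/2 + (i + 0.5) * pixel}
#' (pixel-centre convention). Out-of-grid indices extrapolate linearly.
#'
#' @param grid a \linkS4class{PixelGrid}
#' @param index numeric length-3 \code{(k, j, i)} = (z, y, x) pixel index
#' @return named numeric (x, y, z) in um
#' @export
pixelToPhysical <- function(grid, index) {
  stopifnot(length(index) == 3L)
  idx <- c(x = as.numeric(index[3]), y = as.numeric(index[2]),
           z = as.numeric(index[1]))
  grid@stage + grid@offset - grid@range / 2 + (idx[.axes] + 0.5) * grid@pixel
}

#' Convert stage coordinates to (fractional) pixel indices
#'
#' Inverse of \code{\link{pixelToPhysical}}.
#'
#' @param grid a \linkS4class{PixelGrid}
#' @param point named numeric (x, y, z) in um
#' @return numeric length-3 \code{(k, j, i)} = (z, y, x) 0-based index
#' @export
physicalToPixel <- function(grid, point) {
  point <- .asAxisVec(point[.axes])
  i <- (point - grid@stage - grid@offset + grid@range / 2) / grid@pixel - 0.5
  c(i["z"], i["y"], i["x"])
}

#' Physical box covered by a pixel grid's scan window
#' @param grid a \linkS4class{PixelGrid}
#' @return a \linkS4class{PhysicalBox}
#' @export
gridBox <- function(grid) {
  center <- grid@stage + grid@offset
  physicalBox(center - grid@range / 2, center + grid@range / 2)
}

#' Translate a physical ROI into scan offsets and ranges
#'
#' Detail tasks reuse their parent's stage position; the ROI is expressed as
#' scan offsets relative to that stage position. Ranges are padded to
#' \code{minFov} per axis (so point/degenerate ROIs are valid); an ROI whose
#' scan window would exceed the scanner limits is rejected.
#'
#' @param box a \linkS4class{PhysicalBox}
#' @param stage named numeric (x, y, z): the stage position to scan from
#' @param limits scanner half-range per axis (um); scalar or length 3
#' @param minFov minimum field of view per axis (um); scalar or length 3
#' @return a partial parameter tree with \code{scan/offset} and
#'   \code{scan/range}, or \code{NULL} when the ROI is outside the scanner
#'   limits
#' @export
physicalToScan <- function(box, stage, limits = 40, minFov = 1) {
  stage <- .asAxisVec(stage)
  limits <- .asAxisVec(if (length(limits) == 1L) rep(limits, 3L) else limits)
  minFov <- .asAxisVec(if (length(minFov) == 1L) rep(minFov, 3L) else minFov)
  offset <- boxCenter(box) - stage
  range <- pmax(boxExtent(box), minFov)
  if (any(abs(offset) + range / 2 > limits)) return(NULL)
  list(scan = list(
    offset = list(x = offset[["x"]], y = offset[["y"]], z = offset[["z"]]),
    range = list(x = range[["x"]], y = range[["y"]], z = range[["z"]])))
}

#' Intersection-over-union of two physical boxes
#'
#' 3D volume IoU; 0 for disjoint boxes, 1 for identical boxes. For two
#' degenerate (zero-volume) boxes the result is 1 iff they coincide.
#'
#' @param a,b \linkS4class{PhysicalBox} objects
#' @return a ratio in [0, 1]
#' @export
boxIou <- function(a, b) {
  lo <- pmax(a@minCorner, b@minCorner)
  hi <- pmin(a@maxCorner, b@maxCorner)
  if (any(lo > hi)) return(0)
  inter <- prod(hi - lo)
  union <- prod(boxExtent(a)) + prod(boxExtent(b)) - inter
  if (union <= 0) {
    return(as.numeric(all(a@minCorner == b@minCorner) &&
                      all(a@maxCorner == b@maxCorner)))
  }
  inter / union
}

.pointInBox <- function(point, box) {
  all(point >= box@minCorner) && all(point <= box@maxCorner)
}

#' Create an ROI registry
#'
#' The registry records every region sent to detail imaging; re-detections of
#' the same object (from overlapping overview tiles or repeated callbacks) are
#' discarded. A candidate is discarded iff its IoU with any registered box
#' exceeds \code{iouThreshold} or its centre lies inside a registered box.
#'
#' @param iouThreshold IoU above which a candidate counts as already imaged
#' @return an \linkS4class{ROIRegistry}
#' @export
roiRegistry <- function(iouThreshold = 0.3) {
  state <- new.env(parent = emptyenv())
  state$boxes <- list()
  state$ids <- character(0)
  state$iouThreshold <- iouThreshold
  new("ROIRegistry", state = state)
}

#' Check a candidate ROI against the registry and register it if new
#'
#' @param registry an \linkS4class{ROIRegistry}
#' @param box candidate \linkS4class{PhysicalBox}
#' @param id identifier stored with kept boxes (e.g. the source measurement)
#' @return \code{"kept"} (box appended) or \code{"discarded"}
#' @export
registryCheckAdd <- function(registry, box, id = NA_character_) {
  s <- registry@state
  center <- boxCenter(box)
  for (old in s$boxes) {
    if (boxIou(box, old) > s$iouThreshold || .pointInBox(center, old)) {
      return("discarded")
    }
  }
  s$boxes[[length(s$boxes) + 1L]] <- box
  s$ids <- c(s$ids, id)
  "kept"
}

#' Registered ROI boxes
#' @param registry an \linkS4class{ROIRegistry}
#' @return list of \linkS4class{PhysicalBox}
#' @export
registryBoxes <- function(registry) registry@state$boxes

#' Dump an ROI registry to JSON (audit trail)
#' @param registry an \linkS4class{ROIRegistry}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeRoiRegistry <- function(registry, path) {
  s <- registry@state
  recs <- lapply(seq_along(s$boxes), function(i) {
    b <- s$boxes[[i]]
    list(id = s$ids[i], min = as.list(b@minCorner), max = as.list(b@maxCorner))
  })
  writeLines(as.character(jsonlite::toJSON(
    list(iouThreshold = s$iouThreshold, boxes = recs),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)), path)
  invisible(path)
}
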