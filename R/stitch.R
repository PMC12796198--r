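## Phase correlation and on-the-fly stitching ----------------------------------

#' Integer-pixel phase correlation
#'
#' Finds the translation of \code{moving} relative to \code{reference} by the
#' peak of the inverse transform of the normalized cross-power spectrum. The
#' returned shift \code{(dy, dx)} is the translation such that \code{moving}
#' matches \code{reference} displaced by it. When the correlation peak is
#' below \code{confidenceFloor} (e.g. two unrelated images), the shift falls
#' back to (0, 0).
#'
#' @param reference,moving 2D matrices \code{[y, x]}; unequal shapes are
#'   zero-padded to the common shape
#' @param confidenceFloor minimum normalized peak (1 = perfect match)
#' @return list with integer \code{shift} = c(dy, dx), the correlation
#'   \code{peak}, and a \code{fallback} flag
#' @export
phaseCorrelate <- function(reference, moving, confidenceFloor = 0.05) {
  ny <- max(nrow(reference), nrow(moving))
  nx <- max(ncol(reference), ncol(moving))
  pad <- function(m) {
    out <- matrix(0, ny, nx)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  a <- pad(reference)
  b <- pad(moving)
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  X <- Fa * Conj(Fb)
  R <- X / pmax(Mod(X), 1e-12)
  R[1, 1] <- 0  # drop the uninformative DC term
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  peak <- max(r)
  if (peak < confidenceFloor) {
    return(list(shift = c(dy = 0L, dx = 0L), peak = peak, fallback = TRUE))
  }
  pos <- arrayInd(which.max(r), dim(r)) - 1L  # n with n == -s (mod N)
  wrap <- function(n, N) if (n > N / 2) n - N else n
  n <- c(wrap(pos[1], ny), wrap(pos[2], nx))
  list(shift = c(dy = -n[1], dx = -n[2]), peak = peak, fallback = FALSE)
}

## collapse a grid's z axis so a single-plane mask spans the full z range
.flatGrid <- function(grid) {
  px <- grid@pixel
  px["z"] <- grid@range["z"]
  pixelGrid(grid@stage, grid@offset, grid@range, px)
}

#' Stitch an overview tile with its previously acquired neighbours
#'
#' Selects prior same-level tiles whose scan windows overlap the current
#' tile's (laterally), places everything on a canvas in the current tile's
#' frame based on stage/scan coordinates, and -- when \code{register} is TRUE
#' -- additionally registers each neighbour to the current tile by phase
#' correlation on their overlap region, mitigating stage drift. Overlaps are
#' fused "latest wins" (the newest data are the least drifted); the current
#' tile is painted last and is never shifted. Stitching operates on z-maximum
#' projections; the canvas grid keeps the current tile's z extent as a single
#' thick plane, so detected boxes inherit the overview's z range.
#'
#' @param current the just-acquired overview \linkS4class{Measurement}
#' @param store the \linkS4class{MeasurementStore} holding earlier tiles
#' @param register apply phase-correlation registration to neighbours
#' @param channel channel to project and fuse
#' @param configIndex configuration to use
#' @param confidenceFloor forwarded to \code{\link{phaseCorrelate}}
#' @return a \linkS4class{StitchResult}; with no neighbours the canvas equals
#'   the current tile
#' @export
stitchNeighbors <- function(current, store, register = TRUE, channel = 1L,
                            configIndex = 1L, confidenceFloor = 0.05) {
  proj <- function(meas) {
    st <- stacks(meas)[[configIndex]]
    apply(st[channel, , , , drop = FALSE], c(3, 4), max)
  }
  curGrid <- measurementGrid(current, configIndex)
  curImg <- proj(current)

  qbox <- gridBox(curGrid)
  hits <- queryOverlap(store, levelId(current), qbox, axes = c("x", "y"))
  hits <- Filter(function(h) h$id != measurementId(current), hits)
  if (length(hits) > 0L) {
    hits <- hits[order(vapply(hits, function(h) h$clock, numeric(1)))]
  }

  tiles <- c(unname(lapply(hits, function(h) h$measurement)), list(current))
  grids <- lapply(tiles, measurementGrid, config = configIndex)
  ids <- vapply(tiles, measurementId, character(1), USE.NAMES = FALSE)

  ## canvas lattice aligned with the current tile
  px <- curGrid@pixel
  boxes <- lapply(grids, gridBox)
  unionMin <- Reduce(pmin, lapply(boxes, function(b) b@minCorner))
  unionMax <- Reduce(pmax, lapply(boxes, function(b) b@maxCorner))
  curMin <- qbox@minCorner
  curMax <- qbox@maxCorner
  lo <- curMin
  hi <- curMax
  for (a in c("x", "y")) {
    lo[a] <- curMin[a] - ceiling(round((curMin[a] - unionMin[a]) / px[a], 9)) * px[a]
    hi[a] <- curMax[a] + ceiling(round((unionMax[a] - curMax[a]) / px[a], 9)) * px[a]
  }
  extent <- hi - lo
  center <- (hi + lo) / 2
  canvasPx <- c(px["x"], px["y"], z = unname(curGrid@range["z"]))
  canvasGrid <- pixelGrid(stage = curGrid@stage,
                          offset = center - curGrid@stage,
                          range = c(extent["x"], extent["y"],
                                    z = unname(curGrid@range["z"])),
                          pixel = canvasPx)
  nyC <- canvasGrid@shape[["y"]]
  nxC <- canvasGrid@shape[["x"]]
  canvas <- matrix(0, nyC, nxC)
  provenance <- matrix(0L, nyC, nxC)
  shifts <- stats::setNames(vector("list", length(tiles)), ids)

  place <- function(img, grid, tileIdx, shiftPx = c(dy = 0L, dx = 0L)) {
    origin <- pixelToPhysical(grid, c(0, 0, 0))  # centre of pixel (0,0)
    at <- physicalToPixel(canvasGrid, origin)    # fractional (k, j, i)
    row0 <- as.integer(round(at[2])) - shiftPx[["dy"]]
    col0 <- as.integer(round(at[3])) - shiftPx[["dx"]]
    rSrc <- seq_len(nrow(img)); cSrc <- seq_len(ncol(img))
    rDst <- row0 + rSrc; cDst <- col0 + cSrc       # 1-based dest
    rOk <- rDst >= 1L & rDst <= nyC
    cOk <- cDst >= 1L & cDst <= nxC
    if (!any(rOk) || !any(cOk)) return(invisible(NULL))
    canvas[rDst[rOk], cDst[cOk]] <<- img[rSrc[rOk], cSrc[cOk]]
    provenance[rDst[rOk], cDst[cOk]] <<- tileIdx
    invisible(NULL)
  }

  nTiles <- length(tiles)
  for (t in seq_len(nTiles)) {
    img <- if (t == nTiles) curImg else proj(tiles[[t]])
    shift <- c(dy = 0L, dx = 0L)
    if (register && t < nTiles) {
      est <- .registerToCurrent(curImg, curGrid, img, grids[[t]],
                                confidenceFloor)
      if (!is.null(est)) shift <- est
    }
    shifts[[t]] <- c(x = unname(shift[["dx"]]), y = unname(shift[["dy"]]))
    place(img, grids[[t]], t, shift)
  }

  new("StitchResult", canvas = canvas, grid = canvasGrid, shifts = shifts,
      provenance = provenance, tileIds = ids)
}

## estimate a neighbour's displacement (in px, canvas frame) relative to the
## current tile from their overlap region; NULL when the overlap is too small
.registerToCurrent <- function(curImg, curGrid, nbImg, nbGrid,
                               confidenceFloor) {
  a <- gridBox(curGrid)
  b <- gridBox(nbGrid)
  lo <- pmax(a@minCorner, b@minCorner)
  hi <- pmin(a@maxCorner, b@maxCorner)
  if (any(lo[c("x", "y")] >= hi[c("x", "y")])) return(NULL)
  crop <- function(img, grid) {
    p0 <- physicalToPixel(grid, lo)  # (k, j, i) fractional
    p1 <- physicalToPixel(grid, hi)
    j <- max(1L, floor(p0[2] + 0.5) + 1L):min(nrow(img), ceiling(p1[2] + 0.5))
    i <- max(1L, floor(p0[3] + 0.5) + 1L):min(ncol(img), ceiling(p1[3] + 0.5))
    img[j, i, drop = FALSE]
  }
  ca <- crop(curImg, curGrid)
  cb <- crop(nbImg, nbGrid)
  if (min(dim(ca)) < 8L || min(dim(cb)) < 8L) return(NULL)
  pc <- phaseCorrelate(ca, cb, confidenceFloor = confidenceFloor)
  pc$shift
}
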