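## Default image-analysis building blocks --------------------------------------
##
## Conventions: 2D images are matrices [y, x]; 3D stacks are arrays [z, y, x];
## all pixel coordinates are 0-based (matching the pixel/physical mapping in
## geometry.R) and may be fractional.

#' Difference-of-Gaussians spot detection
#'
#' Local maxima of the DoG response above \code{peakThreshold}, kept greedily
#' in descending response order subject to a pairwise minimum separation;
#' sub-pixel positions by 3-point parabolic refinement per axis. Maxima on the
#' outermost pixel ring are ignored (no refinement possible there).
#'
#' @param image 2D matrix \code{[y, x]}
#' @param sigmaSmall,sigmaLarge DoG Gaussian sigmas in px
#'   (\code{sigmaSmall < sigmaLarge})
#' @param peakThreshold minimum DoG response at a peak
#' @param minSeparation minimum distance between kept peaks (px)
#' @param channel channel id stored with the detections
#' @return a \code{data.frame} with 0-based fractional \code{x}, \code{y},
#'   the DoG \code{response} and the raw image \code{intensity} at the peak
#' @export
dogDetect <- function(image, sigmaSmall = 1.5, sigmaLarge = 3,
                      peakThreshold = 10, minSeparation = 5, channel = 1L) {
  stopifnot(sigmaSmall < sigmaLarge)
  empty <- data.frame(x = numeric(0), y = numeric(0), response = numeric(0),
                      intensity = numeric(0), channel = integer(0))
  if (nrow(image) < 5L || ncol(image) < 5L) return(empty)
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  dog <- EBImage::gblur(img, sigma = sigmaSmall) -
         EBImage::gblur(img, sigma = sigmaLarge)

  ny <- nrow(dog); nx <- ncol(dog)
  core <- dog[2:(ny - 1), 2:(nx - 1)]
  isMax <- core > peakThreshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & (core >= dog[(2 + dy):(ny - 1 + dy),
                                  (2 + dx):(nx - 1 + dx)])
  }
  hits <- which(isMax, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty)
  ry <- hits[, 1] + 1L  # 1-based in full image
  rx <- hits[, 2] + 1L
  resp <- dog[cbind(ry, rx)]
  ord <- order(resp, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) > 0L) {
      d2 <- (ry[keep] - ry[i])^2 + (rx[keep] - rx[i])^2
      if (any(d2 < minSeparation^2)) next
    }
    keep <- c(keep, i)
  }

  refine <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    if (den >= 0) return(0)  # not a proper peak
    max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
  }
  out <- lapply(keep, function(i) {
    cy <- ry[i]; cx <- rx[i]
    dyo <- refine(dog[cy - 1, cx], dog[cy, cx], dog[cy + 1, cx])
    dxo <- refine(dog[cy, cx - 1], dog[cy, cx], dog[cy, cx + 1])
    data.frame(x = cx - 1 + dxo, y = cy - 1 + dyo, response = resp[i],
               intensity = img[cy, cx], channel = as.integer(channel))
  })
  do.call(rbind, out)
}

#' Greedy two-channel spot colocalization
#'
#' One-to-one matching in ascending pair-distance order; pairs farther apart
#' than \code{maxDist} are dropped. Greedy (not optimal-assignment) matching
#' is adequate at typical FISH spot densities.
#'
#' @param a,b spot tables as returned by \code{\link{dogDetect}} (from grids
#'   of identical geometry)
#' @param maxDist maximum pairing distance (px)
#' @return \code{data.frame} of pair centres (midpoints): \code{x}, \code{y},
#'   \code{dist}, and the row indices \code{ia}, \code{ib} of the partners
#' @export
colocalize <- function(a, b, maxDist = 3) {
  empty <- data.frame(x = numeric(0), y = numeric(0), dist = numeric(0),
                      ia = integer(0), ib = integer(0))
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  dist <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
  })
  ord <- order(dist)
  usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
  rows <- list()
  for (k in ord) {
    if (dist[k] > maxDist) break
    ij <- arrayInd(k, dim(dist))
    i <- ij[1]; j <- ij[2]
    if (usedA[i] || usedB[j]) next
    usedA[i] <- TRUE; usedB[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      x = (a$x[i] + b$x[j]) / 2, y = (a$y[i] + b$y[j]) / 2,
      dist = dist[k], ia = i, ib = j)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Threshold + connected-components 3D segmentation
#'
#' 26-connected components of \code{stack > intensityThreshold} with at least
#' \code{minVoxels} voxels, relabelled 1..L in descending size. This is the
#' default segmenter; learned segmenters plug in through the same label-mask
#' contract.
#'
#' @param stack 3D array \code{[z, y, x]} (single channel)
#' @param intensityThreshold voxel intensity threshold
#' @param minVoxels minimum component size
#' @return integer label array, same shape as \code{stack}; 0 = background
#' @export
segment3d <- function(stack, intensityThreshold, minVoxels = 10) {
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  mask <- stack > intensityThreshold
  labels <- array(0L, d)
  visited <- !mask  # background counts as visited
  nz <- d[1]; ny <- d[2]; nx <- d[3]

  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]  # 26 neighbours

  toLinear <- function(k, j, i) k + (j - 1L) * nz + (i - 1L) * nz * ny
  comp <- 0L
  seeds <- which(mask)
  for (seed in seeds) {
    if (visited[seed]) next
    comp <- comp + 1L
    frontier <- seed
    visited[seed] <- TRUE
    while (length(frontier) > 0L) {
      labels[frontier] <- comp
      co <- arrayInd(frontier, d)
      cand <- integer(0)
      for (o in seq_len(nrow(offs))) {
        k <- co[, 1] + offs[o, 1]; j <- co[, 2] + offs[o, 2]
        i <- co[, 3] + offs[o, 3]
        ok <- k >= 1L & k <= nz & j >= 1L & j <= ny & i >= 1L & i <= nx
        if (!any(ok)) next
        lin <- toLinear(k[ok], j[ok], i[ok])
        lin <- lin[!visited[lin]]
        if (length(lin) > 0L) {
          visited[lin] <- TRUE
          cand <- c(cand, lin)
        }
      }
      frontier <- unique(cand)
    }
  }
  if (comp == 0L) return(labels)

  sizes <- tabulate(labels[labels > 0L], nbins = comp)
  keep <- which(sizes >= minVoxels)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(comp)
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  labels
}

#' Physical bounding boxes of label-mask components
#'
#' One tight physical box per label (voxel outer edges). With
#' \code{discardBorder}, labels touching any lateral canvas face (x or y) are
#' dropped -- such objects extend beyond the imaged area and must be skipped
#' (or recovered by stitching).
#'
#' @param mask integer label array \code{[z, y, x]}
#' @param grid the \linkS4class{PixelGrid} the mask lives on
#' @param discardBorder drop labels touching an x/y face
#' @return named list of \linkS4class{PhysicalBox}, names = label ids
#' @export
labelsToBboxes <- function(mask, grid, discardBorder = FALSE) {
  d <- dim(mask)
  if (is.null(d)) {        # 2D matrix: treat as single-plane stack
    mask <- array(mask, c(1L, dim(as.matrix(mask))))
    d <- dim(mask)
  } else if (length(d) == 2L) {
    mask <- array(mask, c(1L, d))
    d <- dim(mask)
  }
  labs <- sort(unique(mask[mask > 0L]))
  out <- list()
  for (lb in labs) {
    co <- arrayInd(which(mask == lb), d)  # 1-based (k, j, i)
    if (discardBorder &&
        (any(co[, 2] == 1L) || any(co[, 2] == d[2]) ||
         any(co[, 3] == 1L) || any(co[, 3] == d[3]))) {
      next
    }
    lo0 <- apply(co, 2, min) - 1L  # 0-based
    hi0 <- apply(co, 2, max) - 1L
    pmin <- pixelToPhysical(grid, lo0 - 0.5)
    pmax <- pixelToPhysical(grid, hi0 + 0.5)
    out[[as.character(lb)]] <- physicalBox(pmin, pmax)
  }
  out
}

#' Pole tiles of a segmented nucleus
#'
#' For each axis, the centroid of the voxels attaining the minimum (resp.
#' maximum) coordinate along that axis becomes a tile centre: six small cubes
#' at the lowest and highest x, y and z positions of the segmented region,
#' replacing a whole-nucleus stack.
#'
#' @param mask logical or integer array \code{[z, y, x]}; non-zero = object
#' @param grid the \linkS4class{PixelGrid} the mask lives on
#' @param tileSize cube side length (um), default 2
#' @return list of 6 \linkS4class{PhysicalBox} (x-min, x-max, y-min, y-max,
#'   z-min, z-max)
#' @export
extractPoles <- function(mask, grid, tileSize = 2) {
  idx <- which(mask > 0)
  if (length(idx) == 0L) stop("empty mask: no poles to extract", call. = FALSE)
  co <- arrayInd(idx, dim(mask))  # (k, j, i) 1-based
  colAxis <- c(z = 1L, y = 2L, x = 3L)
  boxes <- list()
  for (axis in c("x", "y", "z")) {
    v <- co[, colAxis[[axis]]]
    for (extreme in c(min, max)) {
      sel <- co[v == extreme(v), , drop = FALSE]
      centroid0 <- colMeans(sel) - 1  # 0-based (k, j, i)
      center <- pixelToPhysical(grid, centroid0)
      boxes[[length(boxes) + 1L]] <- boxFromCenter(center, tileSize)
    }
  }
  names(boxes) <- c("x-min", "x-max", "y-min", "y-max", "z-min", "z-max")
  ## order: per axis min then max, axes x, y, z
  boxes
}

#' Pre-scan gate: is a field of view informative?
#'
#' Simple intensity criterion: the image passes iff at least
#' \code{countThreshold} pixels exceed \code{intensityThreshold} counts
#' (default: 50 pixels above 50 counts). Uninformative fields of view are
#' skipped with minimal time overhead.
#'
#' @param image array of counts (any shape)
#' @param intensityThreshold counts a pixel must exceed
#' @param countThreshold number of qualifying pixels required
#' @return logical
#' @export
prescanPass <- function(image, intensityThreshold = 50, countThreshold = 50) {
  sum(image > intensityThreshold) >= countThreshold
}

#' Image-based focus update from a z-stack
#'
#' Per-plane focus metric = intensity variance (centre-peaked for extended
#' objects at any area coverage below one half, unlike mean-normalized
#' variants, whose peak moves off-centre once objects cover more than a few
#' percent of the plane); the best plane is found by parabolic interpolation
#' around the metric argmax, and the z correction is
#' \code{(k* - (P-1)/2) * dz}, clamped to \code{+/- maxStep}. When the metric
#' peak-to-mean ratio is below \code{minContrast} (e.g. an empty field of
#' view), confidence is low and the correction is forced to 0.
#'
#' @param stack 3D array \code{[z, y, x]} with at least 3 planes
#' @param dz plane spacing (um)
#' @param maxStep maximum correction magnitude (um)
#' @param minContrast minimum peak-to-mean metric ratio
#' @return list with \code{dz} (um), \code{confident} (logical) and the
#'   per-plane \code{metric}
#' @export
focusUpdate <- function(stack, dz, maxStep = 1, minContrast = 1.05) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[1] >= 3L)
  P <- dim(stack)[1]
  metric <- vapply(seq_len(P), function(k) {
    stats::var(as.numeric(stack[k, , ]))
  }, numeric(1))
  mbar <- mean(metric)
  if (mbar <= 0 || max(metric) / mbar < minContrast) {
    return(list(dz = 0, confident = FALSE, metric = metric))
  }
  k0 <- which.max(metric)
  kstar <- k0 - 1  # 0-based
  if (k0 > 1L && k0 < P) {
    fm <- metric[k0 - 1]; f0 <- metric[k0]; fp <- metric[k0 + 1]
    den <- fm - 2 * f0 + fp
    if (den < 0) kstar <- kstar + max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
  }
  shift <- (kstar - (P - 1) / 2) * dz
  list(dz = max(-maxStep, min(maxStep, shift)), confident = TRUE,
       metric = metric)
}
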