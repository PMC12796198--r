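## Ready-made detectors for detection blocks ------------------------------------

#' Detector: colocalizing two-channel spot pairs
#'
#' Runs difference-of-Gaussians spot detection on the z-maximum projections of
#' two channels of the triggering measurement, pairs the detections greedily
#' (\code{\link{colocalize}}), and returns one small cube per pair centre --
#' the classic DNA-FISH overview-to-detail step.
#'
#' @param channels the two detection channels
#' @param boxSize detail cube side (um), default 2
#' @param maxDistPx maximum pairing distance (px)
#' @param peakThreshold,sigmaSmall,sigmaLarge,minSeparation forwarded to
#'   \code{\link{dogDetect}}
#' @return a detector function for \code{\link{detectionBlock}}
#' @export
colocDetector <- function(channels = c(2, 3), boxSize = 2, maxDistPx = 3,
                          peakThreshold = 15, sigmaSmall = 1, sigmaLarge = 2.5,
                          minSeparation = 3) {
  function(image, grid, state) {
    meas <- lastMeasurement(state)
    st <- stacks(meas)[[1]]
    det <- lapply(channels, function(ch) {
      pr <- apply(st[ch, , , , drop = FALSE], c(3, 4), max)
      dogDetect(pr, sigmaSmall = sigmaSmall, sigmaLarge = sigmaLarge,
                peakThreshold = peakThreshold, minSeparation = minSeparation,
                channel = ch)
    })
    pairs <- colocalize(det[[1]], det[[2]], maxDist = maxDistPx)
    lapply(seq_len(nrow(pairs)), function(r) {
      center <- pixelToPhysical(grid, c(0, pairs$y[r], pairs$x[r]))
      boxFromCenter(center, boxSize)
    })
  }
}

#' Detector: whole nuclei by threshold segmentation
#'
#' Segments the (possibly stitched) 2D overview by threshold + connected
#' components and returns the physical bounding boxes of the labels, dropping
#' objects that touch the lateral image border (they extend beyond the imaged
#' area; on-the-fly stitching recovers them).
#'
#' @param intensityThreshold segmentation threshold (counts)
#' @param minPixels minimum object size (px)
#' @param discardBorder drop border-touching labels
#' @param pad extra margin added around each box (um)
#' @return a detector function for \code{\link{detectionBlock}}
#' @export
nucleusDetector <- function(intensityThreshold = 60, minPixels = 30,
                            discardBorder = TRUE, pad = 0.5) {
  function(image, grid, state) {
    mask <- segment3d(array(image, c(1L, dim(image))),
                      intensityThreshold = intensityThreshold,
                      minVoxels = minPixels)
    boxes <- labelsToBboxes(mask, grid, discardBorder = discardBorder)
    if (pad > 0) {
      boxes <- lapply(boxes, function(b) {
        physicalBox(b@minCorner - c(pad, pad, 0),
                    b@maxCorner + c(pad, pad, 0))
      })
    }
    boxes
  }
}

#' Building block: gate the pipeline on a pre-scan
#'
#' Applies the pre-scan intensity criterion (\code{\link{prescanPass}},
#' default 50 pixels above 50 counts) to the triggering pre-scan measurement.
#' When the field of view is informative the block emits one empty partial
#' tree (letting the other blocks define the follow-up overview); otherwise it
#' vetoes, so the uninformative field of view is skipped.
#'
#' @param channel channel the criterion is evaluated on
#' @param intensityThreshold,countThreshold see \code{\link{prescanPass}}
#' @return a building-block function
#' @export
prescanGateBlock <- function(channel = 1L, intensityThreshold = 50,
                             countThreshold = 50) {
  function(state) {
    meas <- lastMeasurement(state)
    if (is.null(meas)) return(list())
    img <- stacks(meas)[[1]][channel, , , ]
    ok <- prescanPass(img, intensityThreshold = intensityThreshold,
                      countThreshold = countThreshold)
    noteDetections(state, levelId(meas), as.integer(ok))
    if (ok) list(emptyParameterTree()) else list()
  }
}
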