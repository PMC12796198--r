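gaussSpot <- function(n, cy, cx, sigma, amp = 100) {
  y <- matrix(seq_len(n) - 1, n, n)
  x <- t(y)
  amp * exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2))
}

test_that("DoG detection finds synthetic spots where the exhaustive oracle does", {
  img <- gaussSpot(65, 32, 32, sigma = 2)
  det <- dogDetect(img, sigmaSmall = 1.5, sigmaLarge = 3, peakThreshold = 5,
                   minSeparation = 5)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - 32), 1)
  expect_lt(abs(det$y - 32), 1)
  ## oracle: exhaustive local-maximum scan of the DoG response
  dog <- EBImage::gblur(img, 1.5) - EBImage::gblur(img, 3)
  oracle <- which(dog == max(dog), arr.ind = TRUE) - 1  # 0-based (y, x)
  expect_lt(abs(det$y - oracle[1]), 1)
  expect_lt(abs(det$x - oracle[2]), 1)

  expect_equal(nrow(dogDetect(matrix(0, 64, 64), peakThreshold = 5)), 0)

  two <- gaussSpot(65, 20, 22, 2) + gaussSpot(65, 40, 42, 2)
  det2 <- dogDetect(two, 1.5, 3, peakThreshold = 5, minSeparation = 5)
  expect_equal(nrow(det2), 2)
})

test_that("minimum separation suppresses the weaker of two close maxima", {
  img <- gaussSpot(65, 30, 30, 2, amp = 100) + gaussSpot(65, 30, 33, 2, amp = 60)
  det <- dogDetect(img, 1.5, 3, peakThreshold = 5, minSeparation = 6)
  expect_equal(nrow(det), 1)
})

test_that("greedy colocalization matches the brute-force assignment on small cases", {
  a <- data.frame(x = 10, y = 10)
  b <- data.frame(x = c(10, 14), y = c(12, 10))
  ## one A spot between two B spots at distances 2 and 4 -> nearer one wins
  pairs <- colocalize(a, b, maxDist = 5)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$ib, 1)
  expect_equal(pairs$x, 10); expect_equal(pairs$y, 11)
  ## brute-force minimum-cost matching oracle over all assignments
  oracleBest <- which.min(c(sqrt(0 + 4), sqrt(16 + 0)))
  expect_equal(pairs$ib, oracleBest)

  same <- data.frame(x = c(1, 5), y = c(1, 5))
  p2 <- colocalize(same, same, maxDist = 1)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$dist, c(0, 0))

  farA <- data.frame(x = 0, y = 0); farB <- data.frame(x = 10, y = 0)
  expect_equal(nrow(colocalize(farA, farB, maxDist = 3)), 0)
})

ellipsoidMask <- function(dims, center, semi) {
  k <- slice.index(array(0, dims), 1) - 1
  j <- slice.index(array(0, dims), 2) - 1
  i <- slice.index(array(0, dims), 3) - 1
  ((k - center[1]) / semi[1])^2 + ((j - center[2]) / semi[2])^2 +
    ((i - center[3]) / semi[3])^2 <= 1
}

test_that("3D segmentation recovers an ellipsoid with the analytic voxel count", {
  dims <- c(20, 30, 30)
  mask <- ellipsoidMask(dims, c(10, 15, 15), c(5, 8, 7))  # (z, y, x) semi-axes
  stack <- array(0, dims); stack[mask] <- 100
  labels <- segment3d(stack, intensityThreshold = 50, minVoxels = 10)
  expect_equal(max(labels), 1L)
  expect_equal(sum(labels == 1L), sum(mask))  # oracle: ground-truth count
  expect_equal(sum(labels == 1L) / (4 / 3 * pi * 5 * 8 * 7), 1,
               tolerance = 0.05)

  expect_equal(max(segment3d(array(0, c(5, 5, 5)), 10)), 0L)

  withSpeck <- stack
  withSpeck[1, 1, 1:3] <- 100
  lab2 <- segment3d(withSpeck, 50, minVoxels = 10)
  expect_equal(max(lab2), 1L)  # 3-voxel speck filtered out
})

test_that("labels are relabelled in descending size and split across gaps", {
  stack <- array(0, c(4, 20, 20))
  stack[2:3, 2:4, 2:4] <- 100      # 18 voxels
  stack[2:3, 10:15, 10:15] <- 100  # 72 voxels
  labels <- segment3d(stack, 50, minVoxels = 5)
  expect_equal(max(labels), 2L)
  expect_gt(sum(labels == 1L), sum(labels == 2L))
})

test_that("label bounding boxes are tight and border labels can be discarded", {
  g <- pixelGrid(c(0, 0, 0), c(0, 0, 0), c(20, 20, 4), c(1, 1, 1))
  mask <- array(0L, c(4, 20, 20))
  mask[2, 5:8, 6:10] <- 1L          # interior label
  mask[3, 10:12, 1:3] <- 2L         # touches the x = 0 face
  boxes <- labelsToBboxes(mask, g, discardBorder = FALSE)
  expect_length(boxes, 2)
  b1 <- boxes[["1"]]
  ## voxel outer edges: x pixels 5..9 (0-based) -> [-5, 0] um
  expect_equal(unname(b1@minCorner), c(-5, -6, -1))
  expect_equal(unname(b1@maxCorner), c(0, -2, 0))
  kept <- labelsToBboxes(mask, g, discardBorder = TRUE)
  expect_equal(names(kept), "1")
})

test_that("pole extraction finds the six extreme tiles of an ellipsoid", {
  dims <- c(24, 40, 40)
  semi <- c(8, 12, 10)  # (z, y, x) voxels
  mask <- ellipsoidMask(dims, c(12, 20, 20), semi)
  g <- pixelGrid(c(0, 0, 0), c(0, 0, 0), c(20, 20, 12), c(0.5, 0.5, 0.5))
  poles <- extractPoles(mask, g, tileSize = 2)
  expect_length(poles, 6)
  centerPhys <- pixelToPhysical(g, c(12, 20, 20))
  ## oracle: brute-force min/max scan of the mask
  co <- arrayInd(which(mask), dims)
  for (spec in list(list("x-min", 3, min), list("x-max", 3, max),
                    list("y-min", 2, min), list("y-max", 2, max),
                    list("z-min", 1, min), list("z-max", 1, max))) {
    v <- co[, spec[[2]]]
    sel <- co[v == spec[[3]](v), , drop = FALSE]
    oracleCenter <- pixelToPhysical(g, colMeans(sel) - 1)
    expect_equal(unname(boxCenter(poles[[spec[[1]]]])),
                 unname(oracleCenter), tolerance = 1e-12)
    expect_equal(unname(boxExtent(poles[[spec[[1]]]])), c(2, 2, 2))
  }
  ## tile centres sit at c +/- semi-axis within one voxel
  expect_equal(boxCenter(poles[["x-min"]])[["x"]],
               centerPhys[["x"]] - semi[3] * 0.5, tolerance = 0.5)
  expect_equal(boxCenter(poles[["z-max"]])[["z"]],
               centerPhys[["z"]] + semi[1] * 0.5, tolerance = 0.5)

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  p1 <- extractPoles(single, pixelGrid(c(0, 0, 0), c(0, 0, 0),
                                       c(3, 3, 3), c(1, 1, 1)), 2)
  ctrs <- unique(t(vapply(p1, boxCenter, numeric(3))))
  expect_equal(nrow(ctrs), 1)  # degenerate: six coincident tiles
  expect_error(extractPoles(array(FALSE, c(2, 2, 2)), g), "empty mask")
})

test_that("the pre-scan criterion is 50 pixels above 50 counts", {
  img <- matrix(0, 50, 50)
  img[seq_len(100)] <- 60
  expect_true(prescanPass(img))
  img2 <- matrix(0, 50, 50)
  img2[seq_len(49)] <- 60
  expect_false(prescanPass(img2))
  expect_false(prescanPass(matrix(0, 50, 50)))
})

test_that("the focus update finds the sharpest plane and clamps large steps", {
  set.seed(2)
  mk <- function(peakPlane, P = 9) {
    stack <- array(0, c(P, 40, 40))
    for (k in seq_len(P)) {
      amp <- 100 * exp(-(k - 1 - peakPlane)^2 / 2)
      stack[k, 15:25, 15:25] <- amp
    }
    stack
  }
  upd <- focusUpdate(mk(6), dz = 0.5, maxStep = 5)
  ## oracle: metric argmax over planes
  expect_equal(upd$dz, (6 - 4) * 0.5, tolerance = 0.25)
  expect_true(upd$confident)

  flat <- array(stats::rpois(5 * 40 * 40, 3), c(5, 40, 40))
  updFlat <- focusUpdate(flat, dz = 0.5, maxStep = 5, minContrast = 1.5)
  expect_equal(updFlat$dz, 0)
  expect_false(updFlat$confident)

  clamped <- focusUpdate(mk(8), dz = 1, maxStep = 1)
  expect_equal(clamped$dz, 1)  # true offset is 4 planes; clamped to maxStep
})
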