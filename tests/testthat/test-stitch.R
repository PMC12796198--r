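test_that("phase correlation recovers known shifts exactly and detects itself", {
  img <- texturedImage(64, seed = 5)
  self <- phaseCorrelate(img, img)
  expect_equal(unname(self$shift), c(0L, 0L))
  expect_gt(self$peak, 0.9)

  mov <- circShift(img, 5, -3)
  pc <- phaseCorrelate(img, mov)
  expect_equal(unname(pc$shift), c(5L, -3L))
  ## brute-force spatial cross-correlation oracle
  expect_equal(unname(pc$shift), bruteForceShift(img, mov))
})

test_that("phase correlation falls back to zero shift on unrelated noise", {
  set.seed(9)
  a <- matrix(stats::rnorm(128 * 128), 128, 128)
  b <- matrix(stats::rnorm(128 * 128), 128, 128)
  pc <- phaseCorrelate(a, b)
  expect_true(pc$fallback)
  expect_equal(unname(pc$shift), c(0L, 0L))
})

## render a tile measurement directly from a scene
renderTile <- function(scene, x, y, range = c(50, 50, 4), px = 0.4,
                       id = "t1", level = "overview", seq = 1L) {
  ms <- simulatedMicroscope(scene)
  tree <- list(stage = list(x = x, y = y, z = 2),
               scan = list(range = list(x = range[1], y = range[2],
                                        z = range[3]),
                           pixel = list(x = px, y = px, z = 1)),
               mode = "confocal", channels = 1, power = 30, dwell = 1e-5)
  m <- renderMeasurement(ms, acquisitionTask(level, tree), id = id)
  m@sequence <- seq
  m
}

test_that("a lone tile stitches to itself", {
  scene <- generateScene(3, density = 0, extent = c(100, 50),
                         nucleusCenters = list(c(25, 25)))
  store <- measurementStore()
  m <- renderTile(scene, 25, 25)
  saveMeasurement(store, m)
  res <- stitchNeighbors(m, store, register = TRUE)
  proj <- apply(stacks(m)[[1]][1, , , , drop = FALSE], c(3, 4), max)
  expect_equal(res@canvas, proj)
  expect_equal(res@tileIds, "t1")
})

test_that("an object straddling two tiles is one component on the canvas", {
  mk <- function() {
    generateScene(13, extent = c(100, 50), nucleusCenters = list(c(49, 25)),
                  semiAxesXY = c(4.5, 5.5), bodyBrightness = 120,
                  pairSpots = 0)
  }
  scene <- mk()
  store <- measurementStore()
  m1 <- renderTile(scene, 25, 25, id = "t1", seq = 1L)
  saveMeasurement(store, m1)
  m2 <- renderTile(scene, 73, 25, id = "t2", seq = 2L)
  saveMeasurement(store, m2)
  res <- stitchNeighbors(m2, store, register = TRUE)
  lab <- segment3d(array(res@canvas, c(1L, dim(res@canvas))), 60,
                   minVoxels = 30)
  nStitched <- max(lab)
  ## oracle: the same scene rendered as one wide ground-truth mosaic
  oneShot <- renderTile(mk(), 49, 25, range = c(98, 50, 4), id = "w")
  proj <- apply(stacks(oneShot)[[1]][1, , , , drop = FALSE], c(3, 4), max)
  labOracle <- segment3d(array(proj, c(1L, dim(proj))), 60, minVoxels = 30)
  expect_equal(nStitched, max(labOracle))
  expect_equal(nStitched, 1L)
  ## and the stitched box is interior (not border-touching) on the canvas
  boxes <- labelsToBboxes(lab, res@grid, discardBorder = TRUE)
  expect_length(boxes, 1)
})

test_that("registration recovers a neighbour rendered with simulated drift", {
  px <- 0.4
  driftPx <- c(x = 5, y = -3)
  centers <- list(c(40, 25), c(44, 20), c(52, 30))
  mkScene <- function(shift = c(0, 0)) {
    generateScene(21, extent = c(120, 50),
                  nucleusCenters = lapply(centers, function(p) p + shift),
                  semiAxesXY = c(3, 4), bodyBrightness = 120, pairSpots = 0)
  }
  store <- measurementStore()
  ## neighbour imaged earlier, while the sample sat displaced by the drift
  m1 <- renderTile(mkScene(driftPx * px), 25, 25, id = "t1", seq = 1L)
  saveMeasurement(store, m1)
  m2 <- renderTile(mkScene(), 65, 25, id = "t2", seq = 2L)
  saveMeasurement(store, m2)
  res <- stitchNeighbors(m2, store, register = TRUE)
  expect_equal(res@shifts[["t1"]], c(x = 5, y = -3))
  expect_equal(res@shifts[["t2"]], c(x = 0, y = 0))  # current never shifted
})
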