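test_that("scene generation is deterministic given the seed", {
  s1 <- generateScene(17, density = 1, pairSpots = 2, surfaceSpots = 5)
  s2 <- generateScene(17, density = 1, pairSpots = 2, surfaceSpots = 5)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeScene(s1, f1); writeScene(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- generateScene(18, density = 1, pairSpots = 2, surfaceSpots = 5)
  f3 <- withr::local_tempfile(fileext = ".json")
  writeScene(s3, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("scene serialization round-trips through JSON", {
  s1 <- generateScene(17, density = 1, pairSpots = 2, surfaceSpots = 5,
                      tilt = c(0.01, -0.02, 1))
  f1 <- withr::local_tempfile(fileext = ".json")
  writeScene(s1, f1)
  s2 <- readScene(f1)
  expect_equal(length(sceneNuclei(s2)), length(sceneNuclei(s1)))
  expect_equal(sceneSpots(s2)$x, sceneSpots(s1)$x)
  f2 <- withr::local_tempfile(fileext = ".json")
  writeScene(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("nucleus counts follow the requested density", {
  expect_length(sceneNuclei(generateScene(1, density = 0)), 0)
  ## 100 FOV-areas at density 0.5 -> Poisson(50); single draw within 3 sigma
  s <- generateScene(5, density = 0.5, extent = c(500, 500), fovSize = 50)
  n <- length(sceneNuclei(s))
  expect_gt(n, 50 - 3 * sqrt(50))
  expect_lt(n, 50 + 3 * sqrt(50))
})

test_that("zero excitation power leaves only offset and read noise", {
  scene <- generateScene(2, density = 2, extent = c(50, 50), pairSpots = 2)
  ms <- simulatedMicroscope(scene)
  tree <- taskTree(25, 25, 2, range = c(20, 20, 2), pixel = c(0.5, 0.5, 1))
  tree$power <- 0; tree$channels <- 1
  m <- renderMeasurement(ms, acquisitionTask("overview", tree))
  expect_equal(mean(stacks(m)[[1]]), 2, tolerance = 0.1)  # detector offset
})

test_that("a field of view outside the slide renders background only", {
  scene <- generateScene(2, density = 5, extent = c(50, 50))
  ms <- simulatedMicroscope(scene)
  tree <- taskTree(500, 500, 2, range = c(20, 20, 2), pixel = c(0.5, 0.5, 1))
  tree$channels <- 1
  m <- renderMeasurement(ms, acquisitionTask("overview", tree))
  expect_lt(mean(stacks(m)[[1]]), 3)
})

test_that("expected signal is linear in dwell time", {
  scene <- generateScene(3, density = 0, extent = c(50, 50),
                         nucleusCenters = list(c(25, 25)), surfaceSpots = 10)
  p <- taskTree(25, 25, 2.5, range = c(16, 16, 6), pixel = c(0.2, 0.2, 0.5))
  p$channels <- c(1, 2)
  p$dwell <- 1e-5
  e1 <- renderExpectedImage(scene, p)
  p$dwell <- 2e-5
  e2 <- renderExpectedImage(scene, p)
  expect_equal(sum(e2) / sum(e1), 2, tolerance = 1e-9)
})

test_that("the STED point image is sharper than confocal by the sigma ratio", {
  scene <- virtualScene(2, extent = c(20, 20),
                        spots = data.frame(x = 10, y = 10, z = 1,
                                           channel = 1L, brightness = 200,
                                           remaining = 1, nucleus = 1L))
  base <- list(stage = list(x = 10, y = 10, z = 1),
               scan = list(range = list(x = 4, y = 4, z = 0.5),
                           pixel = list(x = 0.01, y = 0.01, z = 0.5)),
               channels = 1)
  fitSigma <- function(e) {
    prof <- e[1, 1, 200, ]  # row through the spot centre
    xs <- (seq_along(prof) - 0.5) * 0.01
    keep <- prof > max(prof) * 0.01
    fit <- stats::lm(log(prof[keep]) ~ xs[keep] + I(xs[keep]^2))
    sqrt(-1 / (2 * stats::coef(fit)[[3]]))
  }
  opt <- opticsModel()
  sConf <- fitSigma(renderExpectedImage(scene, c(base, mode = "confocal"),
                                        opt))
  sSted <- fitSigma(renderExpectedImage(scene, c(base, mode = "sted2d"), opt))
  want <- opt$sigma$confocal[["lat"]] / opt$sigma$sted2d[["lat"]]
  expect_equal(sConf / sSted, want, tolerance = 0.1)
})

test_that("repeated exposure bleaches spots by the closed-form factor", {
  mkScene <- function() {
    virtualScene(4, extent = c(20, 20),
                 spots = data.frame(x = 10, y = 10, z = 1, channel = 1L,
                                    brightness = 200, remaining = 1,
                                    nucleus = 1L))
  }
  scene <- mkScene()
  rates <- bleachRates()
  ms <- simulatedMicroscope(scene, bleach = rates)
  tree <- list(stage = list(x = 10, y = 10, z = 1),
               scan = list(range = list(x = 2, y = 2, z = 1),
                           pixel = list(x = 0.05, y = 0.05, z = 0.25)),
               mode = "sted2d", channels = 1, power = 30, dwell = 1e-5)
  invisible(renderMeasurement(ms, acquisitionTask("detail", tree)))
  rem1 <- sceneSpots(scene)$remaining
  nz <- 4  # planes per exposure; column dose at reference scale
  expect_equal(rem1, bleachFactor(rates$rates[["sted2d"]], 1)^nz,
               tolerance = 1e-12)
  invisible(renderMeasurement(ms, acquisitionTask("detail", tree)))
  expect_equal(sceneSpots(scene)$remaining, rem1^2, tolerance = 1e-12)
})

test_that("bleach factors are multiplicative and dose-free exposure is free", {
  expect_equal(bleachFactor(0.5, 0), 1)
  expect_equal(bleachFactor(0, 100), 1)
  expect_equal(bleachFactor(0.3, 2) , bleachFactor(0.3, 1)^2)
  expect_error(bleachFactor(-1, 1))
})

test_that("drift is zero at t = 0 and for a null model", {
  scene <- generateScene(1, density = 0)
  expect_equal(driftAt(scene, 0), c(x = 0, y = 0, z = 0))
  expect_equal(driftAt(scene, 500), c(x = 0, y = 0, z = 0))
})

test_that("random-walk drift variance grows like sigma^2 t", {
  set.seed(1)
  sigmaRw <- 0.5; T <- 120
  xs <- vapply(seq_len(200), function(i) {
    sc <- virtualScene(1000 + i, drift = list(sigmaRw = sigmaRw,
                                              amplitude = 0, period = 600))
    driftAt(sc, T)[["x"]]
  }, numeric(1))
  ## Monte-Carlo oracle: var = sigma^2 * minutes
  expect_equal(stats::var(xs), sigmaRw^2 * T / 60, tolerance = 0.2)
})

test_that("the simulated clock is monotone and scales with voxel count", {
  scene <- generateScene(1, density = 0)
  ms <- simulatedMicroscope(scene)
  small <- taskTree(10, 10, 1, range = c(5, 5, 1), pixel = c(1, 1, 1))
  big <- taskTree(10, 10, 1, range = c(40, 40, 2), pixel = c(0.5, 0.5, 1))
  t0 <- clockTime(ms)
  invisible(renderMeasurement(ms, acquisitionTask("overview", small)))
  t1 <- clockTime(ms)
  invisible(renderMeasurement(ms, acquisitionTask("overview", big)))
  t2 <- clockTime(ms)
  expect_gt(t1, t0)
  expect_gt(t2 - t1, t1 - t0)
  cm <- clockModel()
  g <- pixelGridFromParameters(small)
  expect_equal(t1 - t0, acquisitionDuration(cm, g, 1e-5, 0))
  waitUntil(ms, t2 + 100)
  expect_equal(clockTime(ms), t2 + 100)
  waitUntil(ms, 0)  # never goes backwards
  expect_equal(clockTime(ms), t2 + 100)
})
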