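test_that("broadcasting repeats singletons, vetoes on empties, rejects mismatches", {
  out <- broadcastCombine(list(list(list(a = 1)),
                               list(list(b = 1), list(b = 2), list(b = 3))))
  expect_length(out, 3)
  expect_equal(out[[2]], list(a = 1, b = 2))

  expect_error(broadcastCombine(list(list(list(a = 1), list(a = 2)),
                                     list(list(b = 1), list(b = 2),
                                          list(b = 3)))),
               "broadcast mismatch")
  expect_length(broadcastCombine(list(list(list(a = 1)), list())), 0)
})

test_that("broadcasting matches a brute-force enumeration oracle", {
  set.seed(11)
  for (rep in 1:30) {
    nBlocks <- sample(1:4, 1)
    n <- sample(2:5, 1)  # the common long length
    lens <- vapply(seq_len(nBlocks), function(i) {
      sample(c(0L, 1L, n), 1, prob = c(0.15, 0.5, 0.35))
    }, integer(1))
    outputs <- lapply(seq_len(nBlocks), function(b) {
      lapply(seq_len(lens[b]), function(i) {
        stats::setNames(list(i), paste0("k", b))
      })
    })
    got <- broadcastCombine(outputs)
    if (any(lens == 0L)) {
      expect_length(got, 0)
    } else {
      expected_n <- max(lens)
      expect_length(got, expected_n)
      ## oracle: direct elementwise construction
      for (i in seq_len(expected_n)) {
        manual <- emptyParameterTree()
        for (b in seq_len(nBlocks)) {
          j <- if (lens[b] == 1L) 1L else i
          manual <- deepMerge(manual, outputs[[b]][[j]])
        }
        expect_identical(got[[i]], manual)
      }
    }
  }
})

test_that("settings blocks load a file once and replay it every invocation", {
  tree <- list(mode = "sted2d", power = 30)
  path <- withr::local_tempfile(fileext = ".json")
  writeParameterTree(tree, path)
  block <- settingsFromFile(path)
  expect_identical(block(NULL), list(autoscope:::.sortTree(tree)))
  expect_identical(block(NULL), block(NULL))
  expect_error(settingsFromFile(file.path(tempdir(), "nope.json")),
               "does not exist")
})

test_that("grid positions walk row-major and veto when exhausted", {
  pb <- positionBlock("grid", origin = c(10, 20), pitch = 5,
                      rows = 2, cols = 3)
  got <- lapply(1:7, function(i) pb(NULL))
  xy <- t(vapply(got[1:6], function(g) {
    c(g[[1]]$stage$x, g[[1]]$stage$y)
  }, numeric(2)))
  expect_equal(xy, cbind(c(10, 15, 20, 10, 15, 20),
                         c(20, 20, 20, 25, 25, 25)))
  expect_length(got[[7]], 0)
})

test_that("the spiral starts at the origin and walks an outward square spiral", {
  pb <- positionBlock("spiral", origin = c(0, 0), pitch = 1)
  xy <- t(vapply(1:9, function(i) {
    g <- pb(NULL)[[1]]$stage
    c(g$x, g$y)
  }, numeric(2)))
  expect_equal(xy[1:5, ], cbind(c(0, 1, 1, 0, -1), c(0, 0, 1, 1, 1)))
  ## all positions distinct (space-filling walk)
  expect_equal(nrow(unique(xy)), 9)
})

test_that("explicit position lists emit in order and then veto", {
  pb <- positionBlock("list", positions = list(c(1, 2), c(3, 4, 5)))
  expect_equal(pb(NULL)[[1]]$stage, list(x = 1, y = 2))
  expect_equal(pb(NULL)[[1]]$stage, list(x = 3, y = 4, z = 5))
  expect_length(pb(NULL), 0)
})

## a loop state with a current measurement, without running a microscope
fakeState <- function(stage = c(4, 5, 6)) {
  state <- new.env()
  state$levels <- twoLevels()
  names(state$levels) <- c("detail", "overview")
  tree <- taskTree(stage[1], stage[2], stage[3])
  state$current <- new("Measurement", id = "m000001", levelId = "overview",
                       sequence = 1L,
                       configurations = list(configuration("main", tree)),
                       stacks = list(array(0, c(1, 2, 10, 10))),
                       acquiredAt = 1, parentId = NA_character_)
  state$emptyStreak <- list()
  state
}

test_that("task generation broadcasts blocks into validated tasks with parents", {
  state <- fakeState()
  roiBlock <- function(state) {
    list(list(scan = list(offset = list(x = 1, y = 1, z = 0),
                          range = list(x = 2, y = 2, z = 2))),
         list(scan = list(offset = list(x = -1, y = 0, z = 0),
                          range = list(x = 2, y = 2, z = 2))))
  }
  gen <- acquisitionTaskGenerator(
    "detail",
    blocks = list(
      settings = settingsBlock(list(scan = list(
        pixel = list(x = 0.1, y = 0.1, z = 0.5)))),
      stage = stagePositionBlock(),
      rois = roiBlock),
    delay = 1.5)
  tasks <- buildTasks(gen, state)
  expect_length(tasks, 2)
  p <- parameters(configurations(tasks[[1]])[[1]])
  expect_equal(treeGet(p, "stage/x"), 4)   # inherited from the parent
  expect_equal(treeGet(p, "scan/offset/x"), 1)
  expect_equal(parentId(tasks[[1]]), "m000001")
  expect_equal(taskDelay(tasks[[2]]), 1.5)
})

test_that("a vetoing block yields no tasks at all", {
  state <- fakeState()
  gen <- acquisitionTaskGenerator(
    "detail",
    blocks = list(settings = settingsBlock(taskTree()),
                  veto = function(state) list()))
  expect_length(buildTasks(gen, state), 0)
})

test_that("configuration variants multiply configurations within one task", {
  state <- fakeState()
  roiBlock <- function(state) {
    lapply(1:3, function(i) {
      list(scan = list(offset = list(x = i, y = 0, z = 0),
                       range = list(x = 2, y = 2, z = 2)))
    })
  }
  gen <- acquisitionTaskGenerator(
    "detail",
    blocks = list(
      settings = settingsBlock(list(
        mode = "confocal",
        scan = list(pixel = list(x = 0.1, y = 0.1, z = 0.5)))),
      stage = stagePositionBlock(),
      rois = roiBlock),
    variants = list(sted2d = list(mode = "sted2d"),
                    sted3d = list(mode = "sted3d")))
  tasks <- buildTasks(gen, state)
  expect_length(tasks, 3)
  confs <- configurations(tasks[[1]])
  expect_length(confs, 2)
  expect_equal(vapply(confs, configurationName, character(1)),
               c("sted2d", "sted3d"))
  expect_equal(treeGet(parameters(confs[[1]]), "mode"), "sted2d")
  expect_equal(treeGet(parameters(confs[[2]]), "mode"), "sted3d")
  ## variants share the base scan window
  expect_equal(treeGet(parameters(confs[[1]]), "scan/offset/x"),
               treeGet(parameters(confs[[2]]), "scan/offset/x"))
})

test_that("blocks with disjoint path sets commute", {
  state <- fakeState()
  s1 <- settingsBlock(list(power = 10))
  s2 <- settingsBlock(list(dwell = 2e-5))
  base <- settingsBlock(taskTree())
  g1 <- acquisitionTaskGenerator("detail", blocks = list(base, s1, s2))
  g2 <- acquisitionTaskGenerator("detail", blocks = list(base, s2, s1))
  t1 <- buildTasks(g1, state)[[1]]
  t2 <- buildTasks(g2, state)[[1]]
  expect_identical(
    autoscope:::.sortTree(parameters(configurations(t1)[[1]])),
    autoscope:::.sortTree(parameters(configurations(t2)[[1]])))
})
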