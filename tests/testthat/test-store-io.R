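mkMeasurement <- function(seq = 1L, level = "overview", nConf = 1L,
                          dims = c(2, 3, 8, 8), stage = c(1, 2, 3)) {
  confs <- list(); stks <- list()
  names <- c("main", "alt")
  for (i in seq_len(nConf)) {
    tree <- taskTree(stage[1], stage[2], stage[3], range = c(8, 8, 3),
                     pixel = c(1, 1, 1))
    confs[[i]] <- configuration(names[i], tree)
    set.seed(seq * 10 + i)
    stks[[i]] <- array(sample(0:4000, prod(dims), replace = TRUE), dims)
  }
  new("Measurement", id = sprintf("m%06d", seq), levelId = level,
      sequence = seq, configurations = confs, stacks = stks,
      acquiredAt = seq * 1.5, parentId = NA_character_)
}

test_that("measurements round-trip losslessly through TIFF plus sidecar", {
  root <- withr::local_tempdir()
  store <- measurementStore(root)
  m <- mkMeasurement(1L, nConf = 2L)
  saveMeasurement(store, m)
  back <- readMeasurementFiles(root, 1L, "overview")
  expect_equal(back@stacks, m@stacks)
  expect_identical(
    autoscope:::.sortTree(parameters(configurations(back)[[1]])),
    autoscope:::.sortTree(parameters(configurations(m)[[1]])))
  expect_equal(acquiredAt(back), acquiredAt(m))
  ## two configurations -> two TIFFs, one sidecar
  files <- list.files(root)
  expect_length(grep("\\.tiff$", files), 2)
  expect_length(grep("\\.json$", files), 1)
})

test_that("store filenames sort lexically in acquisition order", {
  root <- withr::local_tempdir()
  store <- measurementStore(root)
  for (s in c(2L, 10L, 1L)) {
    saveMeasurement(store, mkMeasurement(s))
  }
  tiffs <- sort(grep("tiff$", list.files(root), value = TRUE))
  seqs <- as.integer(sub("_.*", "", tiffs))
  expect_equal(seqs, sort(seqs))
})

test_that("a sequence collision is an error, not a silent overwrite", {
  store <- measurementStore()
  saveMeasurement(store, mkMeasurement(1L))
  expect_error(saveMeasurement(store, mkMeasurement(1L)), "already stored")
})

test_that("overlap queries agree with a brute-force linear scan", {
  set.seed(6)
  store <- measurementStore()
  entries <- list()
  for (s in seq_len(40)) {
    stage <- c(stats::runif(2, 0, 100), 2)
    lv <- sample(c("overview", "detail"), 1)
    m <- mkMeasurement(s, level = lv, stage = stage)
    saveMeasurement(store, m)
    entries[[s]] <- list(level = lv, box = gridBox(measurementGrid(m)),
                         id = measurementId(m))
  }
  for (rep in 1:10) {
    qbox <- boxFromCenter(c(stats::runif(2, 0, 100), 2), c(20, 20, 10))
    hits <- queryOverlap(store, "overview", qbox, axes = c("x", "y"))
    gotIds <- sort(unname(vapply(hits, function(h) h$id, character(1))))
    oracle <- sort(vapply(Filter(function(e) {
      e$level == "overview" &&
        e$box@minCorner[["x"]] < qbox@maxCorner[["x"]] &&
        e$box@maxCorner[["x"]] > qbox@minCorner[["x"]] &&
        e$box@minCorner[["y"]] < qbox@maxCorner[["y"]] &&
        e$box@maxCorner[["y"]] > qbox@minCorner[["y"]]
    }, entries), function(e) e$id, character(1)))
    expect_equal(gotIds, oracle)
  }
})

demoConfig <- function() {
  system.file("extdata", "demo.yaml", package = "autoscope")
}

test_that("the shipped demo config builds a two-level, three-generator pipeline", {
  pl <- loadPipelineConfig(demoConfig(), seed = 1)
  expect_length(pl$levels, 2)
  expect_length(pl$generators, 3)
  expect_equal(queueSize(pl$queue), 1)  # the initial overview
  ## generators are wired onto the overview level
  ovw <- Filter(function(l) l@name == "overview", pl$levels)[[1]]
  expect_length(ovw@callbacks, 3)
})

test_that("config loading fails fast on unknown blocks and broken settings", {
  dir <- withr::local_tempdir()
  cfg <- yaml::read_yaml(demoConfig())
  for (f in c("overview_settings.json", "detail_settings.json",
              "nucleus_settings.json")) {
    file.copy(system.file("extdata", f, package = "autoscope"),
              file.path(dir, f))
  }
  bad <- cfg
  bad$generators[[1]]$blocks[[3]]$type <- "frobnicate"
  yaml::write_yaml(bad, file.path(dir, "bad.yaml"))
  expect_error(loadPipelineConfig(file.path(dir, "bad.yaml")), "frobnicate")

  dup <- cfg
  dup$levels[[2]]$rank <- 1
  yaml::write_yaml(dup, file.path(dir, "dup.yaml"))
  expect_error(loadPipelineConfig(file.path(dir, "dup.yaml")),
               "duplicate level rank")

  ## settings file without pixel sizes: rejected before the loop starts
  broken <- jsonlite::fromJSON(file.path(dir, "overview_settings.json"),
                               simplifyVector = TRUE)
  broken$scan$pixel <- NULL
  writeLines(as.character(jsonlite::toJSON(broken, auto_unbox = TRUE)),
             file.path(dir, "overview_settings.json"))
  yaml::write_yaml(cfg, file.path(dir, "nopixel.yaml"))
  expect_error(loadPipelineConfig(file.path(dir, "nopixel.yaml")),
               "scan/pixel")
})

test_that("the CLI runs a pipeline deterministically and summarizes it", {
  out <- withr::local_tempdir()
  code <- cliRun(c("run", demoConfig(), "--max-images", "4", "--seed", "1",
                   "--out", out))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "log.jsonl")))
  expect_true(file.exists(file.path(out, "focus_map.csv")))
  expect_true(file.exists(file.path(out, "roi_registry.json")))
  recs <- lapply(readLines(file.path(out, "log.jsonl")), jsonlite::fromJSON)
  acq <- Filter(function(r) identical(r$event, "acquisition"), recs)
  expect_length(acq, 4)
  expect_equal(cliRun(c("summarize", out)), 0L)
})

test_that("a blank sample halts the CLI run through the no-objects stop", {
  dir <- withr::local_tempdir()
  expect_equal(cliRun(c("make-scene", "--seed", "2", "--density", "0",
                        "--out", file.path(dir, "scene.json"))), 0L)
  cfg <- yaml::read_yaml(demoConfig())
  cfg$backend <- list(type = "sim", scene = "scene.json", seed = 2)
  for (f in c("overview_settings.json", "detail_settings.json",
              "nucleus_settings.json")) {
    file.copy(system.file("extdata", f, package = "autoscope"),
              file.path(dir, f))
  }
  yaml::write_yaml(cfg, file.path(dir, "blank.yaml"))
  out <- file.path(dir, "out")
  expect_equal(cliRun(c("run", file.path(dir, "blank.yaml"),
                        "--out", out)), 0L)
  recs <- lapply(readLines(file.path(out, "log.jsonl")), jsonlite::fromJSON)
  stopRec <- Filter(function(r) identical(r$event, "stop"), recs)[[1]]
  expect_match(stopRec$outcome, "no-objects")
})

test_that("unknown subcommands and missing configs exit non-zero", {
  expect_equal(cliRun(c("frobnicate")), 1L)
  expect_equal(cliRun(c("run", "/nonexistent/config.yaml")), 1L)
})
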