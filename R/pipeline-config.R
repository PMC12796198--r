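## Pipeline configuration: YAML -> a runnable pipeline ---------------------------
##
## A pipeline YAML names hierarchy levels (unique ranks), attaches generators
## (built from registered building-block names) to levels, selects the
## backend, and seeds the queue with initial task(s). Only registered block
## names are allowed -- no arbitrary code loading from configuration.

.builtinBlocks <- function() {
  list(
    settings_file = function(p, ctx) {
      settingsFromFile(file.path(ctx$dir, p$path))
    },
    settings = function(p, ctx) settingsBlock(p$tree),
    positions = function(p, ctx) {
      positionBlock(mode = p$mode %||% "grid",
                    origin = as.numeric(p$origin %||% c(0, 0)),
                    pitch = p$pitch, rows = p$rows, cols = p$cols,
                    positions = p$positions)
    },
    stage_inherit = function(p, ctx) stagePositionBlock(),
    focus_update = function(p, ctx) {
      focusBlock(channel = p$channel %||% 1L,
                 maxStep = p$max_step %||% 1,
                 minContrast = p$min_contrast %||% 1.05)
    },
    prescan_gate = function(p, ctx) {
      prescanGateBlock(channel = p$channel %||% 1L,
                       intensityThreshold = p$intensity_threshold %||% 50,
                       countThreshold = p$count_threshold %||% 50)
    },
    detect_coloc = function(p, ctx) {
      detectionBlock(
        colocDetector(channels = as.integer(p$channels %||% c(2, 3)),
                      boxSize = p$box_size %||% 2,
                      maxDistPx = p$max_dist_px %||% 3,
                      peakThreshold = p$peak_threshold %||% 15),
        selector = lastImageSelector(channel = (p$channels %||% c(2, 3))[[1]]),
        registry = ctx$registry,
        limits = p$limits %||% 40, minFov = p$min_fov %||% 1)
    },
    detect_nuclei = function(p, ctx) {
      sel <- if (isTRUE(p$stitch)) {
        stitchedSelector(ctx$store, channel = p$channel %||% 1L,
                         register = !isFALSE(p$register))
      } else {
        lastImageSelector(channel = p$channel %||% 1L)
      }
      detectionBlock(
        nucleusDetector(intensityThreshold = p$intensity_threshold %||% 60,
                        minPixels = p$min_pixels %||% 30,
                        discardBorder = !isFALSE(p$discard_border)),
        selector = sel, registry = ctx$registry,
        limits = p$limits %||% 40, minFov = p$min_fov %||% 1)
    })
}

#' Load and construct a pipeline from a YAML configuration
#'
#' Instantiates hierarchy levels, generators (from registered building-block
#' names), stopping criteria, the backend and the initial task(s), failing
#' fast -- before the loop starts -- on unknown block names, duplicate ranks
#' or invalid/missing settings.
#'
#' @param path path to the pipeline YAML
#' @param seed optional seed overriding the configuration's
#' @param outDir optional output directory (store root); NULL = in-memory
#' @return a list: \code{queue}, \code{levels}, \code{microscope},
#'   \code{stops}, \code{store}, \code{registry}, \code{scene}, \code{config}
#' @export
loadPipelineConfig <- function(path, seed = NULL, outDir = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("pipeline config '%s' does not exist", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))

  if (is.null(cfg$levels) || length(cfg$levels) == 0L) {
    stop("config has no levels", call. = FALSE)
  }
  ranks <- vapply(cfg$levels, function(l) as.integer(l$rank), integer(1))
  if (anyDuplicated(ranks)) {
    stop("duplicate level rank in config", call. = FALSE)
  }

  seed <- as.integer(seed %||% cfg$backend$seed %||% 1L)
  scene <- .buildScene(cfg$backend, dir, seed)
  microscope <- simulatedMicroscope(scene)
  store <- measurementStore(root = if (!is.null(outDir)) {
    file.path(outDir, "measurements")
  } else NULL)
  registry <- roiRegistry(iouThreshold = cfg$dedup_iou %||% 0.3)
  ctx <- list(dir = dir, store = store, registry = registry)

  registryFns <- .builtinBlocks()
  gens <- list()
  for (g in cfg$generators %||% list()) {
    blocks <- lapply(g$blocks, function(b) {
      fn <- registryFns[[b$type %||% ""]]
      if (is.null(fn)) {
        stop(sprintf("unknown building block '%s' in generator '%s'",
                     b$type %||% "<missing type>", g$name %||% "?"),
             call. = FALSE)
      }
      fn(b, ctx)
    })
    variants <- lapply(g$variants %||% list(), .normalizeTree)
    gens[[length(gens) + 1L]] <- list(
      after = g$after,
      generator = acquisitionTaskGenerator(
        targetLevel = g$target, blocks = blocks, variants = variants,
        delay = g$delay %||% 0, name = g$name %||% g$target))
  }

  levels <- lapply(cfg$levels, function(l) {
    cbs <- lapply(Filter(function(g) identical(g$after, l$name), gens),
                  function(g) g$generator)
    hierarchyLevel(l$name, l$rank, callbacks = cbs)
  })
  queue <- taskQueue(levels)

  stops <- lapply(cfg$stops %||% list(), function(s) {
    if (identical(s$kind, "no_objects")) {
      stopWhenNothingFound(s$count, s$level)
    } else {
      makeStoppingCriterion(s$kind, n = s$count, t = s$seconds)
    }
  })

  for (init in cfg$initial %||% list()) {
    tree <- if (!is.null(init$settings)) {
      readParameterTree(file.path(dir, init$settings))
    } else emptyParameterTree()
    if (!is.null(init$position)) {
      p <- as.numeric(init$position)
      tree <- deepMerge(tree, list(stage = list(
        x = p[1], y = p[2], z = if (length(p) >= 3) p[3] else 0)))
    }
    task <- acquisitionTask(init$level, tree)
    validateTask(task, levels)  # fail before the loop starts
    enqueueTask(queue, task, clock = 0)
  }

  list(queue = queue, levels = levels, microscope = microscope,
       stops = stops, store = store, registry = registry, scene = scene,
       config = cfg, generators = lapply(gens, `[[`, "generator"))
}

.buildScene <- function(backend, dir, seed) {
  backend <- backend %||% list(type = "sim")
  if (!identical(backend$type %||% "sim", "sim")) {
    stop(sprintf("unknown backend '%s' (only 'sim' is built in)",
                 backend$type), call. = FALSE)
  }
  if (!is.null(backend$scene) && is.character(backend$scene)) {
    return(readScene(file.path(dir, backend$scene)))
  }
  g <- backend$generate %||% list()
  generateScene(seed = seed,
                density = g$density %||% 1,
                extent = as.numeric(g$extent %||% c(250, 250)),
                fovSize = g$fov_size %||% 50,
                surfaceSpots = g$surface_spots %||% 0,
                pairSpots = g$pair_spots %||% 2,
                tilt = as.numeric(g$tilt %||% c(0, 0, 0)),
                drift = list(sigmaRw = g$drift_sigma %||% 0,
                             amplitude = g$drift_amplitude %||% 0,
                             period = g$drift_period %||% 600))
}
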