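## Shared fixtures, built in code at test time.

## a minimal complete task parameter tree
taskTree <- function(x = 0, y = 0, z = 0, range = c(10, 10, 2),
                     pixel = c(1, 1, 1)) {
  list(stage = list(x = x, y = y, z = z),
       scan = list(range = list(x = range[1], y = range[2], z = range[3]),
                   pixel = list(x = pixel[1], y = pixel[2], z = pixel[3])))
}

twoLevels <- function() {
  list(hierarchyLevel("detail", 1L), hierarchyLevel("overview", 2L))
}

## random canonical parameter tree; shape at each path is determined by the
## key alone, so any two generated trees are free of structural conflicts
randomTree <- function(depth = 0) {
  keys <- sample(c("g1", "g2", "l1", "l2", "l3", "l4"),
                 size = sample(2:5, 1))
  out <- list()
  for (k in unique(keys)) {
    if (startsWith(k, "g") && depth < 2) {
      out[[k]] <- randomTree(depth + 1)
    } else if (!startsWith(k, "g")) {
      out[[k]] <- switch(sample(3, 1),
        stats::runif(1) * 100,
        paste0("s", sample(99, 1)),
        stats::runif(sample(2:4, 1)))
    }
  }
  if (length(out) == 0L) out <- list(l1 = 1.5)
  out
}

## scripted two-level pipeline: each overview's callbacks enqueue two detail
## tasks at the same position and the next overview, on tiny frames
oddoPipeline <- function(seed, nOverviews = 2, storeRoot = NULL) {
  scene <- generateScene(seed, density = 0, extent = c(50, 50))
  microscope <- simulatedMicroscope(scene)
  store <- measurementStore(root = storeRoot)
  small <- taskTree(25, 25, 1, range = c(8, 8, 1), pixel = c(1, 1, 1))
  counter <- new.env(); counter$n <- 1L
  addTasks <- function(state) {
    tasks <- list(
      acquisitionTask("detail", small,
                      parentId = measurementId(state$current)),
      acquisitionTask("detail", small,
                      parentId = measurementId(state$current)))
    if (counter$n < nOverviews) {
      counter$n <- counter$n + 1L
      tasks <- c(tasks, list(acquisitionTask("overview", small)))
    }
    tasks
  }
  levels <- list(hierarchyLevel("detail", 1L),
                 hierarchyLevel("overview", 2L,
                                callbacks = list(addTasks)))
  queue <- taskQueue(levels)
  enqueueTask(queue, acquisitionTask("overview", small), clock = 0)
  list(queue = queue, levels = levels, microscope = microscope,
       store = store)
}

## brute-force circular cross-correlation oracle for phase correlation
bruteForceShift <- function(reference, moving, maxShift = 10) {
  circ <- function(m, dy, dx) {
    ny <- nrow(m); nx <- ncol(m)
    m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
  }
  best <- c(0, 0); bestCor <- -Inf
  for (dy in -maxShift:maxShift) {
    for (dx in -maxShift:maxShift) {
      cc <- sum(moving * circ(reference, dy, dx))
      if (cc > bestCor) {
        bestCor <- cc
        best <- c(dy, dx)
      }
    }
  }
  best
}

## textured test image (smoothed noise)
texturedImage <- function(n = 64, seed = 1) {
  set.seed(seed)
  EBImage::gblur(matrix(stats::rnorm(n * n), n, n), 2)
}

circShift <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}
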