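## Parameter trees ------------------------------------------------------------
##
## Measurement parameters travel through the package as plain nested named
## lists ("parameter trees"), mirroring how point-scanning microscope control
## software exposes its measurement state as a dictionary. Subtrees are named
## lists; leaves are scalars (numeric, character, logical) or flat vectors /
## unnamed lists. The canonical path schema used throughout:
##
##   stage$x, stage$y, stage$z        stage position (um)
##   scan$offset$x/y/z                scan offsets relative to the
##                                    stage-centred field of view (um)
##   scan$range$x/y/z                 scan ranges (um), > 0
##   scan$pixel$x/y/z                 pixel sizes (um), > 0
##   mode                             "confocal" | "sted2d" | "sted3d"
##   channels                         detection channel ids recorded
##   power                            excitation power (percent)
##   dwell                            pixel dwell time (s)
##
## A backend adapter is expected to map these canonical paths onto its own
## namespace; everything inside this package speaks only the canonical schema.

#' @import methods
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## A node is a subtree iff it is a (possibly empty) fully-named list;
## unnamed lists and atomic vectors are leaves.
.isSubtree <- function(x) {
  is.list(x) && (length(x) == 0L ||
    (!is.null(names(x)) && all(nzchar(names(x)))))
}

#' Create an empty parameter tree
#' @return an empty named list usable as a parameter tree
#' @export
emptyParameterTree <- function() {
  structure(list(), names = character(0))
}

#' Recursively merge two parameter trees
#'
#' Produces a tree containing every path of both inputs. Subtrees are merged
#' recursively; on a leaf conflict the \code{override} value wins; list/vector
#' leaves are replaced wholesale, never concatenated. Inputs are not mutated.
#' \code{deepMerge} is associative on conflict-free inputs and has the empty
#' tree as identity.
#'
#' @param base,override parameter trees (nested named lists)
#' @return the merged parameter tree
#' @export
deepMerge <- function(base, override) {
  .deepMerge(base, override, character(0))
}

.deepMerge <- function(base, override, path) {
  if (!.isSubtree(base) || !.isSubtree(override)) {
    stop("deepMerge() expects named-list parameter trees", call. = FALSE)
  }
  out <- base
  for (nm in names(override)) {
    here <- paste(c(path, nm), collapse = "/")
    o <- override[[nm]]
    if (is.null(o)) {
      stop(sprintf("NULL value at '%s' is not a valid parameter leaf", here),
           call. = FALSE)
    }
    if (!nm %in% names(base)) {
      out[[nm]] <- o
      next
    }
    b <- base[[nm]]
    bSub <- .isSubtree(b)
    oSub <- .isSubtree(o)
    if (bSub && oSub) {
      out[[nm]] <- .deepMerge(b, o, c(path, nm))
    } else if (!bSub && !oSub) {
      out[[nm]] <- o
    } else {
      stop(sprintf("structural conflict at '%s': scalar vs. subtree", here),
           call. = FALSE)
    }
  }
  out
}

#' Look up a value in a parameter tree by path
#'
#' @param tree a parameter tree
#' @param path slash-separated path, e.g. \code{"scan/range/x"}
#' @return the value at the path, or \code{NULL} if absent
#' @export
treeGet <- function(tree, path) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  node <- tree
  for (k in keys) {
    if (!.isSubtree(node) || !k %in% names(node)) return(NULL)
    node <- node[[k]]
  }
  node
}

#' Set a value in a parameter tree by path
#'
#' Intermediate subtrees are created as needed; returns a modified copy.
#'
#' @param tree a parameter tree
#' @param path slash-separated path
#' @param value leaf value to store
#' @return the modified tree
#' @export
treeSet <- function(tree, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  patch <- value
  for (k in rev(keys)) {
    wrap <- list()
    wrap[[k]] <- patch
    patch <- wrap
  }
  deepMerge(tree, patch)
}

.sortTree <- function(tree) {
  if (!.isSubtree(tree)) return(tree)
  if (length(tree) == 0L) return(emptyParameterTree())
  tree <- tree[order(names(tree))]
  lapply(tree, .sortTree)
}

## normalize a parsed tree: integers -> doubles so serialize/parse round-trips
## to an identical() object
.normalizeTree <- function(x) {
  if (.isSubtree(x)) return(lapply(x, .normalizeTree))
  if (is.integer(x)) return(as.double(x))
  x
}

#' Validate a parameter tree
#'
#' Checks structural validity (unique names at each level, no NULL leaves) and
#' domain constraints: all \code{scan/range} and \code{scan/pixel} entries must
#' be strictly positive where present.
#'
#' @param tree a parameter tree
#' @return the tree, invisibly; errors describe the offending path
#' @export
validateParameterTree <- function(tree) {
  .validateNode(tree, character(0))
  invisible(tree)
}

.validateNode <- function(node, path) {
  if (.isSubtree(node)) {
    if (anyDuplicated(names(node))) {
      stop(sprintf("duplicate keys under '%s'", paste(path, collapse = "/")),
           call. = FALSE)
    }
    for (nm in names(node)) .validateNode(node[[nm]], c(path, nm))
    return(invisible(NULL))
  }
  here <- paste(path, collapse = "/")
  if (is.null(node)) stop(sprintf("NULL leaf at '%s'", here), call. = FALSE)
  if (is.function(node)) {
    stop(sprintf("function leaf at '%s'", here), call. = FALSE)
  }
  parent <- if (length(path) >= 2L) path[length(path) - 1L] else ""
  if (parent %in% c("range", "pixel") && length(path) >= 3L &&
      path[length(path) - 2L] == "scan") {
    if (!is.numeric(node) || any(!is.finite(node)) || any(node <= 0)) {
      stop(sprintf("'%s' must be a positive finite number", here),
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Serialize a parameter tree to canonical JSON
#'
#' Keys are sorted recursively so that equal trees serialize identically;
#' numbers are written at full precision, so serialize/parse is the identity.
#'
#' @param tree a parameter tree
#' @return a length-1 character JSON string
#' @export
parameterTreeToJSON <- function(tree) {
  as.character(jsonlite::toJSON(.sortTree(tree), auto_unbox = TRUE,
                                digits = I(17), null = "null"))
}

#' Parse a parameter tree from JSON text
#' @param text JSON text (as written by \code{parameterTreeToJSON})
#' @return a parameter tree
#' @export
parameterTreeFromJSON <- function(text) {
  .normalizeTree(jsonlite::fromJSON(text, simplifyVector = TRUE))
}

#' Read / write a parameter tree as a JSON file
#' @param path file path
#' @return \code{readParameterTree}: the tree. \code{writeParameterTree}:
#'   the path, invisibly.
#' @export
readParameterTree <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("settings file '%s' does not exist", path), call. = FALSE)
  }
  tree <- parameterTreeFromJSON(paste(readLines(path, warn = FALSE),
                                      collapse = "\n"))
  validateParameterTree(tree)
  tree
}

#' @rdname readParameterTree
#' @param tree a parameter tree
#' @export
writeParameterTree <- function(tree, path) {
  writeLines(parameterTreeToJSON(tree), path)
  invisible(path)
}

## Paths every complete acquisition task must carry (per configuration).
requiredTaskPaths <- function() {
  c("stage/x", "stage/y", "stage/z",
    "scan/range/x", "scan/range/y", "scan/range/z",
    "scan/pixel/x", "scan/pixel/y", "scan/pixel/z")
}
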