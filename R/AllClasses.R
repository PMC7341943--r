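## Core S4 containers for traced rhizoid systems.

.SWC_LABELS <- c("thallus", "apophysis", "rhizoid", "unknown")
.SWC_COLUMNS <- c("id", "label", "x", "y", "z", "radius", "parent")

#' TracedTree: a rooted geometric tree parsed from SWC
#'
#' A `TracedTree` holds one traced rhizoid system as a node table in SWC
#' order of fields: node id, structure label (`thallus`, `apophysis`,
#' `rhizoid`, `unknown`), coordinates in micrometres, local radius in
#' micrometres and the parent node id (`-1` marks the root, by convention
#' the thallus centre). The graph must be a single rooted tree: ids unique,
#' every non-root parent present, all nodes reachable from the one root.
#'
#' @slot nodes data.frame with columns `id`, `label`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @slot cellId character scalar identifying the cell.
#' @slot frameTime numeric scalar, hours since the start of imaging
#'   (`NA` when the tree is not part of a time series).
#'
#' @seealso [readSWC()], [morphometry()], [rhizoidTimeSeries()]
#' @export
setClass("TracedTree",
         slots = c(nodes = "data.frame",
                   cellId = "character",
                   frameTime = "numeric"))

## Pointer-doubling reachability: with one root and every parent resolvable,
## the node table is a tree iff every chain of parents reaches the root.
.allReachRoot <- function(parentRow, rootRow) {
  n <- length(parentRow)
  anc <- parentRow
  anc[rootRow] <- rootRow
  for (i in seq_len(ceiling(log2(max(n, 2))) + 1L)) anc <- anc[anc]
  all(anc == rootRow)
}

setValidity("TracedTree", function(object) {
  nd <- object@nodes
  if (!all(.SWC_COLUMNS %in% names(nd)))
    return(paste("nodes must have columns:", paste(.SWC_COLUMNS, collapse = ", ")))
  if (nrow(nd) < 1L) return("tree must contain at least one node")
  if (anyDuplicated(nd$id)) return("node ids must be unique")
  if (any(nd$id <= 0L)) return("node ids must be positive")
  if (!all(nd$label %in% .SWC_LABELS))
    return(paste("labels must be one of:", paste(.SWC_LABELS, collapse = ", ")))
  if (!all(is.finite(nd$x)) || !all(is.finite(nd$y)) || !all(is.finite(nd$z)))
    return("coordinates must be finite")
  if (any(!is.finite(nd$radius)) || any(nd$radius < 0))
    return("radii must be finite and non-negative")
  rootRow <- which(nd$parent == -1L)
  if (length(rootRow) != 1L)
    return(sprintf("exactly one root (parent = -1) required, found %d", length(rootRow)))
  parentRow <- match(nd$parent, nd$id)
  dangling <- is.na(parentRow) & nd$parent != -1L
  if (any(dangling))
    return(sprintf("dangling parent reference(s) at node id(s): %s",
                   paste(nd$id[dangling], collapse = ", ")))
  if (any(nd$parent == nd$id)) return("node cannot be its own parent")
  parentRow[rootRow] <- rootRow
  if (!.allReachRoot(parentRow, rootRow))
    return("node table contains a cycle or disconnected component")
  if (length(object@cellId) != 1L) return("cellId must be a single string")
  if (length(object@frameTime) != 1L) return("frameTime must be a single number")
  TRUE
})

#' Construct a TracedTree from a node table
#'
#' @param nodes data.frame with columns `id`, `label`, `x`, `y`, `z`,
#'   `radius`, `parent`. `id` and `parent` are coerced to integer.
#' @param cellId cell identifier.
#' @param frameTime frame timestamp in hours, or `NA`.
#' @return A validated [TracedTree-class] object.
#' @examples
#' nd <- data.frame(id = 1:2, label = c("thallus", "rhizoid"),
#'                  x = c(0, 10), y = 0, z = 0, radius = c(2.5, 0.25),
#'                  parent = c(-1L, 1L))
#' TracedTree(nd, cellId = "germling")
#' @export
TracedTree <- function(nodes, cellId = "cell", frameTime = NA_real_) {
  nodes <- as.data.frame(nodes)[, .SWC_COLUMNS]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$label <- as.character(nodes$label)
  for (cc in c("x", "y", "z", "radius")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  rownames(nodes) <- NULL
  obj <- new("TracedTree", nodes = nodes, cellId = as.character(cellId),
             frameTime = as.numeric(frameTime))
  obj
}

setMethod("show", "TracedTree", function(object) {
  nd <- object@nodes
  cat(sprintf("TracedTree '%s': %d nodes (%d rhizoid, %d thallus)%s\n",
              object@cellId, nrow(nd),
              sum(nd$label %in% c("rhizoid", "apophysis", "unknown")),
              sum(nd$label == "thallus"),
              if (is.na(object@frameTime)) "" else
                sprintf(", t = %g h", object@frameTime)))
})

#' RhizoidTimeSeries: timestamped snapshots of one growing cell
#'
#' Frames are [TracedTree-class] snapshots of the same cell at strictly
#' increasing times (hours). When `idStable` is `TRUE` (always true for
#' simulator output) node ids persist across frames, so branch events can
#' be located by identity rather than spatial matching.
#'
#' @slot frames list of `TracedTree`, each with a non-missing `frameTime`.
#' @slot idStable logical flag: node ids persist across frames.
#' @export
setClass("RhizoidTimeSeries",
         slots = c(frames = "list", idStable = "logical"))

setValidity("RhizoidTimeSeries", function(object) {
  if (length(object@frames) < 1L) return("at least one frame required")
  if (!all(vapply(object@frames, function(f) is(f, "TracedTree"), logical(1))))
    return("all frames must be TracedTree objects")
  tt <- vapply(object@frames, function(f) f@frameTime, numeric(1))
  if (any(is.na(tt))) return("every frame must carry a frameTime")
  if (length(tt) > 1L && any(diff(tt) <= 0))
    return("frame times must be strictly increasing")
  if (length(object@idStable) != 1L) return("idStable must be a single flag")
  TRUE
})

#' Construct a RhizoidTimeSeries
#'
#' @param frames list of [TracedTree-class] snapshots.
#' @param times optional numeric vector of frame times (hours); overrides
#'   any `frameTime` already stored in the trees.
#' @param idStable do node ids persist across frames?
#' @return A validated [RhizoidTimeSeries-class].
#' @export
rhizoidTimeSeries <- function(frames, times = NULL, idStable = TRUE) {
  if (is(frames, "TracedTree")) frames <- list(frames)
  if (!is.null(times)) {
    stopifnot(length(times) == length(frames))
    frames <- mapply(function(f, t) { f@frameTime <- as.numeric(t); f },
                     frames, times, SIMPLIFY = FALSE)
  }
  new("RhizoidTimeSeries", frames = frames, idStable = isTRUE(idStable))
}

setMethod("show", "RhizoidTimeSeries", function(object) {
  tt <- frameTimes(object)
  cat(sprintf("RhizoidTimeSeries '%s': %d frames, t = %g..%g h, ids %s\n",
              cellId(object@frames[[1]]), length(tt), min(tt), max(tt),
              if (object@idStable) "stable" else "unstable"))
})

#' RasterGrid: binary raster of a projected rhizoid system
#'
#' @slot pixels logical matrix; rows index y, columns index x.
#' @slot pixelSize pixel edge length in micrometres.
#' @slot origin numeric length-2, micrometre coordinates (x, y) of the
#'   centre of pixel `[1, 1]`.
#' @export
setClass("RasterGrid",
         slots = c(pixels = "matrix", pixelSize = "numeric", origin = "numeric"))

setValidity("RasterGrid", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (length(object@origin) != 2L) return("origin must be length-2 (x, y)")
  TRUE
})

#' @rdname RasterGrid-class
#' @param pixels logical matrix (rows = y, cols = x).
#' @param pixelSize pixel size in micrometres.
#' @param origin micrometre (x, y) of pixel `[1, 1]`.
#' @export
rasterGrid <- function(pixels, pixelSize = 1, origin = c(0, 0)) {
  new("RasterGrid", pixels = pixels, pixelSize = as.numeric(pixelSize),
      origin = as.numeric(origin))
}

setMethod("show", "RasterGrid", function(object) {
  cat(sprintf("RasterGrid: %d x %d px at %g um/px, %d foreground\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              sum(object@pixels)))
})

#' FractalResult: global and windowed box-counting dimension
#'
#' @slot dbGlobal global box-counting dimension of the full grid.
#' @slot fitR2 R-squared of the log-log fit behind `dbGlobal`.
#' @slot boxSizes box sizes (pixels) used for the global fit.
#' @slot counts occupied-box counts matching `boxSizes`.
#' @slot dbMap matrix of local Db values (NA where a window held too few
#'   foreground pixels); empty matrix when only the global fit was run.
#' @slot windowPx,stridePx sliding-window size and stride in pixels.
#' @slot centresX,centresY micrometre coordinates of window centres
#'   (columns / rows of `dbMap`).
#' @slot pixelSize pixel size of the source grid (micrometres).
#' @export
setClass("FractalResult",
         slots = c(dbGlobal = "numeric", fitR2 = "numeric",
                   boxSizes = "numeric", counts = "numeric",
                   dbMap = "matrix", windowPx = "numeric", stridePx = "numeric",
                   centresX = "numeric", centresY = "numeric",
                   pixelSize = "numeric"))

setMethod("show", "FractalResult", function(object) {
  cat(sprintf("FractalResult: Db = %.3f (R2 = %.3f, %d box sizes)",
              object@dbGlobal, object@fitR2, length(object@boxSizes)))
  if (length(object@dbMap) > 0)
    cat(sprintf("; local map %d x %d windows (%d defined)",
                nrow(object@dbMap), ncol(object@dbMap),
                sum(!is.na(object@dbMap))))
  cat("\n")
})

#' GrowthRateEstimate: per-cell slopes and group statistics
#'
#' @slot metric morphometric name the slopes refer to.
#' @slot slopes named numeric vector of per-cell OLS slopes (units h^-1).
#' @slot groupMean,groupSd,groupSem group mean, s.d. and s.e.m. of slopes.
#' @slot nCells number of cells contributing slopes.
#' @export
setClass("GrowthRateEstimate",
         slots = c(metric = "character", slopes = "numeric",
                   groupMean = "numeric", groupSd = "numeric",
                   groupSem = "numeric", nCells = "integer"))

setMethod("show", "GrowthRateEstimate", function(object) {
  cat(sprintf("GrowthRateEstimate [%s]: %.4g +/- %.4g (s.e.m., n = %d cells)\n",
              object@metric, object@groupMean, object@groupSem, object@nCells))
})
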