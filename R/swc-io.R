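## SWC reading/writing and planar projection.
##
## SWC is the 7-column whitespace text format of the neuron-tracing world:
##   id type x y z radius parent
## "#" starts a comment. Coordinates and radii are taken as micrometres.
## Type codes are mapped onto the chytrid cell plan: 1 = thallus (soma code),
## 5 = apophysis, 3 = rhizoid (dendrite code), anything else = unknown.
## Unknown compartments are measured as rhizoid; only the thallus is excluded
## from rhizoid-specific metrics.

.SWC_TYPE_TO_LABEL <- c("1" = "thallus", "5" = "apophysis", "3" = "rhizoid")
.SWC_LABEL_TO_TYPE <- c(thallus = 1L, apophysis = 5L, rhizoid = 3L, unknown = 0L)

.labelFromType <- function(type) {
  lab <- .SWC_TYPE_TO_LABEL[as.character(type)]
  lab[is.na(lab)] <- "unknown"
  unname(lab)
}

#' Read a traced rhizoid system from an SWC file
#'
#' Parses a standard 7-column SWC file into a [TracedTree-class]. Nodes may
#' appear in any order (a two-pass parse resolves forward parent
#' references); the structure is validated on construction, so dangling
#' parent references, cycles and multiple roots are rejected.
#'
#' @param path path to an SWC file.
#' @param cellId cell identifier; defaults to the file name without
#'   extension.
#' @param frameTime frame timestamp in hours, or `NA`. When `NA`, a
#'   `# frame_time <hours>` header comment (written by [writeSWC()]) is
#'   honoured if present.
#' @return A [TracedTree-class].
#' @examples
#' f <- tempfile(fileext = ".swc")
#' writeLines(c("# toy", "1 1 0 0 0 2.5 -1", "2 3 0 10 0 0.25 1"), f)
#' readSWC(f)
#' @seealso [writeSWC()], [projectXY()]
#' @export
readSWC <- function(path, cellId = NULL, frameTime = NA_real_) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (is.na(frameTime)) {
    ft <- grep("^#\\s*frame_time\\b", raw, value = TRUE)
    if (length(ft) > 0)
      frameTime <- suppressWarnings(as.numeric(sub("^#\\s*frame_time\\s+", "", ft[1])))
  }
  keep <- !grepl("^\\s*(#|$)", raw)
  lineNo <- which(keep)
  dataLines <- trimws(raw[keep])
  if (length(dataLines) == 0L) stop("no data lines in SWC file: ", path)
  fields <- strsplit(dataLines, "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop(sprintf("malformed SWC line %d in %s: expected 7 fields, found %d",
                 lineNo[which(nf != 7L)[1]], path, nf[nf != 7L][1]))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop(sprintf("malformed SWC line %d in %s: non-numeric field", lineNo[bad], path))
  }
  nd <- data.frame(id = as.integer(m[, 1]),
                   label = .labelFromType(as.integer(m[, 2])),
                   x = m[, 3], y = m[, 4], z = m[, 5],
                   radius = m[, 6],
                   parent = as.integer(m[, 7]))
  if (is.null(cellId)) cellId <- sub("\\.[sS][wW][cC]$", "", basename(path))
  TracedTree(nd, cellId = cellId, frameTime = frameTime)
}

#' Write a traced tree to a standard SWC file
#'
#' Nodes are written parents-before-children (re-ordered if necessary); the
#' header records the unit convention and, when available, the frame time so
#' that [readSWC()] can round-trip it.
#'
#' @param tree a [TracedTree-class].
#' @param path output file path.
#' @param digits significant digits for coordinates and radii.
#' @return `path`, invisibly.
#' @export
writeSWC <- function(tree, path, digits = 10) {
  stopifnot(is(tree, "TracedTree"))
  nd <- tree@nodes
  if (nrow(nd) == 0L) stop("empty tree: nothing to serialize")
  ix <- .treeIndex(tree)
  ord <- order(.nodeDepths(ix))                 # parents before children
  nd <- nd[ord, , drop = FALSE]
  hdr <- c("# SWC traced rhizoid system", "# units micrometres",
           sprintf("# cell_id %s", tree@cellId))
  if (!is.na(tree@frameTime))
    hdr <- c(hdr, sprintf("# frame_time %.10g", tree@frameTime))
  fmt <- function(v) sprintf(paste0("%.", digits, "g"), v)
  lines <- sprintf("%d %d %s %s %s %s %d",
                   nd$id, .SWC_LABEL_TO_TYPE[nd$label],
                   fmt(nd$x), fmt(nd$y), fmt(nd$z), fmt(nd$radius),
                   nd$parent)
  con <- file(path, open = "wb")                # LF endings on every platform
  on.exit(close(con))
  writeLines(c(hdr, lines), con)
  invisible(path)
}

#' Project a traced tree onto the focal (XY) plane
#'
#' Returns one 2-D segment per parent-child edge with z discarded —
#' the geometry underlying cover area, rasterization and box counting,
#' mirroring analysis on maximum-intensity projections.
#'
#' @param tree a [TracedTree-class].
#' @return data.frame with columns `x0`, `y0`, `x1`, `y1` (micrometres),
#'   one row per edge; zero rows for a single-node tree.
#' @export
projectXY <- function(tree) {
  stopifnot(is(tree, "TracedTree"))
  ix <- .treeIndex(tree)
  data.frame(x0 = ix$pos[ix$edgeParent, 1], y0 = ix$pos[ix$edgeParent, 2],
             x1 = ix$pos[ix$edgeChild, 1], y1 = ix$pos[ix$edgeChild, 2])
}
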