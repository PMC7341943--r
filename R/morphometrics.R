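## Morphometric glossary for a single traced rhizoid system.
##
## Conventions shared by all metrics:
##  * the thallus root anchors the tree but is not rhizoid material: edges
##    whose child is labelled "thallus" are excluded from length and surface
##    area, and the root is never a tip or a bifurcation;
##  * apophysis and unknown compartments are measured as rhizoid;
##  * degenerate zero-length edges are dropped before any computation.

#' Total rhizoid length
#'
#' Sum of Euclidean edge lengths over all edges whose child node is not
#' labelled `thallus`. A root-only germling has length 0.
#'
#' @param tree a [TracedTree-class].
#' @return length in micrometres.
#' @export
totalLength <- function(tree) {
  ix <- .treeIndex(.dropZeroEdges(tree))
  keep <- ix$nd$label[ix$edgeChild] != "thallus"
  sum(ix$edgeLen[keep])
}

#' Count rhizoid tips and bifurcations
#'
#' Tips are non-root nodes with no children; bifurcations are nodes with two
#' or more children, the root excluded. For strictly binary branching,
#' tips = bifurcations + 1.
#'
#' @param tree a [TracedTree-class].
#' @return named integer vector `c(n_tips, n_bifurcations)`.
#' @export
countTipsBifurcations <- function(tree) {
  ix <- .treeIndex(.dropZeroEdges(tree))
  notRoot <- seq_len(ix$n) != ix$rootRow
  c(n_tips = sum(ix$nChild == 0L & notRoot),
    n_bifurcations = sum(ix$nChild >= 2L & notRoot))
}

#' @rdname countTipsBifurcations
#' @export
nTips <- function(tree) unname(countTipsBifurcations(tree)["n_tips"])

#' @rdname countTipsBifurcations
#' @export
nBifurcations <- function(tree) unname(countTipsBifurcations(tree)["n_bifurcations"])

#' Rhizoidal growth unit (RGU)
#'
#' The growth-unit metric adapted from the hyphal growth unit: higher RGU
#' means a less branched system. Two definitions are provided:
#' `"ratio"` (the default, Trinci's comparative form) is total rhizoid
#' length divided by tip number; `"segment"` is the mean path length
#' between consecutive critical points (root, bifurcations, tips), i.e. the
#' literal mean inter-branch-point distance. Since the segments partition
#' the edge set, the segment form equals (total edge length) /
#' (n_tips + n_bifurcations).
#'
#' @param tree a [TracedTree-class].
#' @param method `"ratio"` or `"segment"`.
#' @return RGU in micrometres. `NA` (with a warning) for the segment method
#'   on an unbranched tree, and for the ratio method on a tree without tips.
#' @export
rgu <- function(tree, method = c("ratio", "segment")) {
  method <- match.arg(method)
  tree <- .dropZeroEdges(tree)
  cnt <- countTipsBifurcations(tree)
  if (method == "ratio") {
    if (cnt["n_tips"] == 0L) {
      warning("ratio RGU undefined: tree has no tips")
      return(NA_real_)
    }
    return(totalLength(tree) / unname(cnt["n_tips"]))
  }
  ix <- .treeIndex(tree)
  branched <- any(ix$nChild >= 2L)               # root counts as a segment split
  if (!branched) {
    warning("segment RGU undefined: tree has no branch points")
    return(NA_real_)
  }
  sum(ix$edgeLen) / unname(cnt["n_tips"] + cnt["n_bifurcations"])
}

#' Rhizoid surface area
#'
#' Each non-thallus edge contributes the lateral surface of a conical
#' frustum, pi * (r_parent + r_child) * slant, with
#' slant = sqrt(axial^2 + (r_parent - r_child)^2). With
#' `includeThallus = TRUE` the thallus root adds a sphere of its radius —
#' provided separately because reported cell surface areas may or may not
#' include the cell body.
#'
#' @param tree a [TracedTree-class].
#' @param includeThallus add the root sphere (4 pi r^2)?
#' @return area in square micrometres.
#' @export
surfaceArea <- function(tree, includeThallus = FALSE) {
  ix <- .treeIndex(.dropZeroEdges(tree))
  keep <- ix$nd$label[ix$edgeChild] != "thallus"
  rp <- ix$nd$radius[ix$edgeParent[keep]]
  rc <- ix$nd$radius[ix$edgeChild[keep]]
  slant <- sqrt(ix$edgeLen[keep]^2 + (rp - rc)^2)
  area <- sum(pi * (rp + rc) * slant)
  if (includeThallus) area <- area + 4 * pi * ix$nd$radius[ix$rootRow]^2
  area
}

#' Maximum Euclidean distance
#'
#' Longest straight-line distance from the thallus root to any node — the
#' reach of the rhizoid system.
#'
#' @param tree a [TracedTree-class].
#' @return distance in micrometres (0 for a root-only tree).
#' @export
maxEuclidean <- function(tree) {
  ix <- .treeIndex(.dropZeroEdges(tree))
  d <- sqrt(colSums((t(ix$pos) - ix$pos[ix$rootRow, ])^2))
  max(d)
}

#' Local bifurcation angles
#'
#' At every bifurcation (root excluded) the angle between the direction
#' vectors of each pair of daughters. A daughter's direction is the chord
#' from the branch point to the first node on its path at least `minOffset`
#' micrometres away (path length), which suppresses quantization noise in
#' densely sampled traces; if the daughter path ends or branches earlier,
#' its last unambiguous node is used.
#'
#' @param tree a [TracedTree-class].
#' @param minOffset minimum path offset in micrometres for the direction
#'   chord (default 0.5).
#' @return numeric vector of angles in degrees (empty if no bifurcations).
#' @export
bifurcationAngles <- function(tree, minOffset = 0.5) {
  tree <- .dropZeroEdges(tree)
  ix <- .treeIndex(tree)
  ci <- .childIndex(ix)
  elen <- numeric(ix$n)
  elen[ix$edgeChild] <- ix$edgeLen
  bifs <- which(ix$nChild >= 2L & seq_len(ix$n) != ix$rootRow)
  if (length(bifs) == 0L) return(numeric(0))
  chord <- function(b, k) {
    acc <- elen[k]
    cur <- k
    while (acc < minOffset && ix$nChild[cur] == 1L) {
      nxt <- .kidsOf(ci, cur, ix$nChild)
      acc <- acc + elen[nxt]
      cur <- nxt
    }
    v <- ix$pos[cur, ] - ix$pos[b, ]
    v / sqrt(sum(v^2))
  }
  out <- vector("list", length(bifs))
  for (i in seq_along(bifs)) {
    b <- bifs[i]
    kids <- .kidsOf(ci, b, ix$nChild)
    dirs <- vapply(kids, function(k) chord(b, k), numeric(3))
    pairs <- utils::combn(length(kids), 2)
    ang <- apply(pairs, 2, function(p) {
      cs <- sum(dirs[, p[1]] * dirs[, p[2]])
      acos(max(-1, min(1, cs))) * 180 / pi
    })
    out[[i]] <- ang
  }
  unlist(out)
}

#' Cover area
#'
#' Area of the 2-D convex hull of the XY-projected node positions — the
#' territory the rhizoid system spans. Degenerate systems (fewer than three
#' non-collinear projected points) cover zero area.
#'
#' @param tree a [TracedTree-class].
#' @return area in square micrometres.
#' @export
coverArea <- function(tree) {
  ix <- .treeIndex(.dropZeroEdges(tree))
  xy <- unique(ix$pos[, 1:2, drop = FALSE])
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3L) return(0)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * (c(hy[-1], hy[1])) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Full morphometric record for one traced tree
#'
#' Applies the whole metric suite and returns a one-row data.frame suitable
#' for row-binding across cells or frames. Undefined metrics (for example
#' RGU on a root-only germling) are recorded as `NA` rather than raising.
#'
#' @param tree a [TracedTree-class].
#' @param minOffset path offset for bifurcation-angle chords (micrometres).
#' @return one-row data.frame with columns `cell_id`, `frame_time`,
#'   `total_length`, `n_tips`, `n_bifurcations`, `rgu_ratio`, `rgu_segment`,
#'   `surface_area`, `surface_area_total`, `max_euclidean`,
#'   `mean_bif_angle`, `cover_area`.
#' @examples
#' nd <- data.frame(id = 1:4, label = c("thallus", rep("rhizoid", 3)),
#'                  x = c(0, 0, 6, -6), y = c(0, 10, 18, 18), z = 0,
#'                  radius = c(2.5, .25, .25, .25), parent = c(-1L, 1L, 2L, 2L))
#' morphometry(TracedTree(nd))
#' @export
morphometry <- function(tree, minOffset = 0.5) {
  stopifnot(is(tree, "TracedTree"))
  tree <- .dropZeroEdges(tree)
  cnt <- countTipsBifurcations(tree)
  ang <- bifurcationAngles(tree, minOffset = minOffset)
  data.frame(
    cell_id = tree@cellId,
    frame_time = tree@frameTime,
    total_length = totalLength(tree),
    n_tips = unname(cnt["n_tips"]),
    n_bifurcations = unname(cnt["n_bifurcations"]),
    rgu_ratio = if (cnt["n_tips"] > 0) totalLength(tree) / unname(cnt["n_tips"]) else NA_real_,
    rgu_segment = suppressWarnings(rgu(tree, "segment")),
    surface_area = surfaceArea(tree, includeThallus = FALSE),
    surface_area_total = surfaceArea(tree, includeThallus = TRUE),
    max_euclidean = maxEuclidean(tree),
    mean_bif_angle = if (length(ang)) mean(ang) else NA_real_,
    cover_area = coverArea(tree))
}
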