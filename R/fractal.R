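## Box-counting fractal dimension of the projected rhizoid system.
##
## The traced skeleton is rasterized as 1-pixel-wide digital line strokes
## (fluorescence intensity plays no role), occupied boxes are counted over a
## geometric series of box sizes, and Db is the negative slope of the
## log-log least-squares fit. A sliding-window variant maps local Db to
## resolve the centre-to-edge gradient of rhizoid systems.

#' Rasterize projected segments onto a binary pixel grid
#'
#' Each 2-D segment is drawn as a 1-pixel-wide digital line (rounded linear
#' interpolation over max(|dx|, |dy|) + 1 samples). The grid is padded by
#' one pixel of margin on every side.
#'
#' @param segments data.frame with columns `x0`, `y0`, `x1`, `y1`
#'   (micrometres), e.g. from [projectXY()]; a [TracedTree-class] is
#'   accepted and projected automatically.
#' @param pixelSize pixel edge length in micrometres (default 0.5,
#'   approximately confocal lateral sampling).
#' @return A [RasterGrid-class].
#' @export
rasterizeSegments <- function(segments, pixelSize = 0.5) {
  if (is(segments, "TracedTree")) segments <- projectXY(segments)
  stopifnot(pixelSize > 0)
  if (nrow(segments) == 0L) stop("empty segment set: nothing to rasterize")
  pad <- 1L
  xmin <- min(segments$x0, segments$x1); ymin <- min(segments$y0, segments$y1)
  toCol <- function(x) as.integer(round((x - xmin) / pixelSize)) + 1L + pad
  toRow <- function(y) as.integer(round((y - ymin) / pixelSize)) + 1L + pad
  c0 <- toCol(segments$x0); c1 <- toCol(segments$x1)
  r0 <- toRow(segments$y0); r1 <- toRow(segments$y1)
  ncol <- max(c0, c1) + pad
  nrow <- max(r0, r1) + pad
  grid <- matrix(FALSE, nrow, ncol)
  for (i in seq_len(length(c0))) {
    ns <- max(abs(c1[i] - c0[i]), abs(r1[i] - r0[i])) + 1L
    cc <- as.integer(round(seq(c0[i], c1[i], length.out = ns)))
    rr <- as.integer(round(seq(r0[i], r1[i], length.out = ns)))
    grid[cbind(rr, cc)] <- TRUE
  }
  rasterGrid(grid, pixelSize = pixelSize,
             origin = c(xmin - pad * pixelSize, ymin - pad * pixelSize))
}

## Occupied-box counts for foreground pixel coordinates (rows, cols).
.boxCounts <- function(coords, sizes) {
  vapply(sizes, function(s) {
    bi <- (coords[, 1] - 1L) %/% s
    bj <- (coords[, 2] - 1L) %/% s
    length(unique(bi * (max(bj) + 2) + bj))
  }, numeric(1))
}

.dbFit <- function(sizes, counts) {
  fit <- stats::lm(log(counts) ~ log(sizes))
  ## summary() warns on numerically perfect fits (exact power laws)
  r2 <- if (stats::var(log(counts)) > 0)
    suppressWarnings(summary(fit)$r.squared) else 1
  list(db = -unname(stats::coef(fit)[2]), r2 = r2)
}

.defaultSizes <- function(dims) {
  smax <- min(dims) / 4
  k <- floor(log2(smax))
  if (k < 1) return(numeric(0))
  2^(1:k)
}

#' Global box-counting dimension
#'
#' Counts occupied boxes N(s) over a geometric series of box sizes s and
#' reports Db = -slope of the least-squares fit of log N(s) on log s,
#' together with the fit R-squared. Db is ~1 for a line, ~2 for a filled
#' plane, ~0 for a point.
#'
#' @param grid a [RasterGrid-class].
#' @param sizes box sizes in pixels; default: powers of 2 from 2 px up to a
#'   quarter of the grid's short side. At least 4 sizes are required.
#' @return A [FractalResult-class] with the global fields populated.
#' @export
boxCountDb <- function(grid, sizes = NULL) {
  stopifnot(is(grid, "RasterGrid"))
  coords <- which(grid@pixels, arr.ind = TRUE)
  if (nrow(coords) == 0L) stop("empty grid: no foreground pixels")
  if (is.null(sizes)) sizes <- .defaultSizes(dim(grid@pixels))
  if (length(sizes) < 4L)
    stop("need at least 4 box sizes (grid too small for the default series)")
  counts <- .boxCounts(coords, sizes)
  fit <- .dbFit(sizes, counts)
  new("FractalResult", dbGlobal = fit$db, fitR2 = fit$r2,
      boxSizes = as.numeric(sizes), counts = counts,
      dbMap = matrix(numeric(0), 0, 0), windowPx = NA_real_,
      stridePx = NA_real_, centresX = numeric(0), centresY = numeric(0),
      pixelSize = grid@pixelSize)
}

#' Spatially resolved (sliding-window) box-counting dimension
#'
#' Applies [boxCountDb()] in square windows placed on a stride grid.
#' Windows with fewer than `minPixels` foreground pixels are reported as
#' missing. The global fit over the whole grid is computed alongside.
#'
#' @param grid a [RasterGrid-class].
#' @param windowPx window side in pixels (default 64); must be at least 4x
#'   the smallest box size and no larger than the grid.
#' @param stridePx stride between window origins in pixels (default 16).
#' @param minPixels minimum foreground pixels for a defined window.
#' @return A [FractalResult-class] with `dbMap` (rows = y, cols = x) and
#'   window-centre coordinates in micrometres.
#' @export
localDbMap <- function(grid, windowPx = 64, stridePx = 16, minPixels = 10) {
  stopifnot(is(grid, "RasterGrid"))
  dims <- dim(grid@pixels)
  if (windowPx > min(dims)) stop("window larger than grid")
  sizes <- 2^(1:max(1, floor(log2(windowPx / 4))))
  if (windowPx < 4 * min(sizes)) stop("window must be >= 4x smallest box size")
  coords <- which(grid@pixels, arr.ind = TRUE)
  if (nrow(coords) == 0L) stop("empty grid: no foreground pixels")
  rowStarts <- seq(1L, dims[1] - windowPx + 1L, by = stridePx)
  colStarts <- seq(1L, dims[2] - windowPx + 1L, by = stridePx)
  dbMap <- matrix(NA_real_, length(rowStarts), length(colStarts))
  for (i in seq_along(rowStarts)) {
    inRow <- coords[, 1] >= rowStarts[i] & coords[, 1] < rowStarts[i] + windowPx
    sub <- coords[inRow, , drop = FALSE]
    for (j in seq_along(colStarts)) {
      w <- sub[sub[, 2] >= colStarts[j] & sub[, 2] < colStarts[j] + windowPx, ,
               drop = FALSE]
      if (nrow(w) < minPixels) next
      local <- cbind(w[, 1] - rowStarts[i] + 1L, w[, 2] - colStarts[j] + 1L)
      dbMap[i, j] <- .dbFit(sizes, .boxCounts(local, sizes))$db
    }
  }
  glob <- boxCountDb(grid)
  new("FractalResult", dbGlobal = glob@dbGlobal, fitR2 = glob@fitR2,
      boxSizes = glob@boxSizes, counts = glob@counts,
      dbMap = dbMap, windowPx = as.numeric(windowPx),
      stridePx = as.numeric(stridePx),
      centresX = grid@origin[1] + (colStarts + (windowPx - 1) / 2 - 1) * grid@pixelSize,
      centresY = grid@origin[2] + (rowStarts + (windowPx - 1) / 2 - 1) * grid@pixelSize,
      pixelSize = grid@pixelSize)
}

#' Radial profile of local fractal dimension
#'
#' Mean local Db per concentric annulus about a centre point (usually the
#' thallus), quantifying the centre-to-growing-edge fractal gradient.
#'
#' @param result a [FractalResult-class] from [localDbMap()].
#' @param centre numeric length-2, micrometre (x, y) of the annulus centre.
#' @param binWidth annulus width in micrometres; defaults to half the
#'   window size.
#' @return data.frame with `r_inner`, `r_outer`, `r_mid`, `mean_db`,
#'   `n_windows`; annuli containing no defined window have `mean_db = NA`.
#' @export
radialDbProfile <- function(result, centre, binWidth = NULL) {
  stopifnot(is(result, "FractalResult"))
  if (length(result@dbMap) == 0L) stop("no local Db map: run localDbMap() first")
  def <- !is.na(result@dbMap)
  if (!any(def)) stop("no defined local Db values")
  if (is.null(binWidth)) binWidth <- result@windowPx * result@pixelSize / 2
  cx <- matrix(result@centresX, nrow(result@dbMap), ncol(result@dbMap), byrow = TRUE)
  cy <- matrix(result@centresY, nrow(result@dbMap), ncol(result@dbMap))
  r <- sqrt((cx - centre[1])^2 + (cy - centre[2])^2)
  rMax <- max(r[def])
  edges <- seq(0, rMax + binWidth, by = binWidth)
  bin <- findInterval(r[def], edges, rightmost.closed = TRUE)
  vals <- result@dbMap[def]
  nb <- length(edges) - 1L
  meanDb <- rep(NA_real_, nb)
  nW <- integer(nb)
  agg <- tapply(vals, bin, mean)
  cnt <- tapply(vals, bin, length)
  idx <- as.integer(names(agg))
  meanDb[idx] <- agg
  nW[idx] <- cnt
  data.frame(r_inner = edges[-length(edges)], r_outer = edges[-1],
             r_mid = (edges[-length(edges)] + edges[-1]) / 2,
             mean_db = meanDb, n_windows = nW)
}
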