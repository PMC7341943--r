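# Naive brute-force re-implementations of every morphometric, used as
# independent oracles. All of them work node-by-node with explicit scans
# and recursion — no shared code with the package internals.

.oKids <- function(nd, id) nd$id[!is.na(nd$parent) & nd$parent == id & nd$parent != -1L]
.oRow <- function(nd, id) which(nd$id == id)
.oPos <- function(nd, id) unlist(nd[.oRow(nd, id), c("x", "y", "z")])
.oDist <- function(nd, a, b) sqrt(sum((.oPos(nd, a) - .oPos(nd, b))^2))

# drop zero-length edges the slow way: contract child into parent
.oClean <- function(nd) {
  repeat {
    bad <- NULL
    for (i in seq_len(nrow(nd))) {
      if (nd$parent[i] == -1L) next
      if (.oDist(nd, nd$id[i], nd$parent[i]) == 0) { bad <- i; break }
    }
    if (is.null(bad)) return(nd)
    cid <- nd$id[bad]; pid <- nd$parent[bad]
    nd$parent[nd$parent == cid] <- pid
    nd <- nd[-bad, , drop = FALSE]
  }
}

oracleTotalLength <- function(tree) {
  nd <- .oClean(swcNodes(tree))
  s <- 0
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L || nd$label[i] == "thallus") next
    s <- s + .oDist(nd, nd$id[i], nd$parent[i])
  }
  s
}

oracleCounts <- function(tree) {
  nd <- .oClean(swcNodes(tree))
  rootId <- nd$id[nd$parent == -1L]
  tips <- 0L; bifs <- 0L
  for (i in seq_len(nrow(nd))) {
    id <- nd$id[i]
    k <- length(.oKids(nd, id))
    if (id == rootId) next
    if (k == 0L) tips <- tips + 1L
    if (k >= 2L) bifs <- bifs + 1L
  }
  c(n_tips = tips, n_bifurcations = bifs)
}

oracleMaxEuclidean <- function(tree) {
  nd <- .oClean(swcNodes(tree))
  rootId <- nd$id[nd$parent == -1L]
  best <- 0
  for (id in nd$id) best <- max(best, .oDist(nd, rootId, id))
  best
}

oracleSurfaceArea <- function(tree, includeThallus = FALSE) {
  nd <- .oClean(swcNodes(tree))
  s <- 0
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L || nd$label[i] == "thallus") next
    rp <- nd$radius[.oRow(nd, nd$parent[i])]
    rc <- nd$radius[i]
    ax <- .oDist(nd, nd$id[i], nd$parent[i])
    s <- s + pi * (rp + rc) * sqrt(ax^2 + (rp - rc)^2)
  }
  if (includeThallus) s <- s + 4 * pi * nd$radius[nd$parent == -1L]^2
  s
}

# enumerate inter-critical-point segments explicitly by recursive descent
oracleSegmentLengths <- function(tree) {
  nd <- .oClean(swcNodes(tree))
  rootId <- nd$id[nd$parent == -1L]
  isCritical <- function(id) {
    id == rootId || length(.oKids(nd, id)) != 1L
  }
  segs <- c()
  descend <- function(startId) {
    for (k in .oKids(nd, startId)) {
      len <- .oDist(nd, startId, k)
      cur <- k
      while (!isCritical(cur)) {
        nxt <- .oKids(nd, cur)
        len <- len + .oDist(nd, cur, nxt)
        cur <- nxt
      }
      segs <<- c(segs, len)
      descend(cur)
    }
  }
  descend(rootId)
  segs
}

oracleRguSegment <- function(tree) {
  nd <- .oClean(swcNodes(tree))
  rootId <- nd$id[nd$parent == -1L]
  if (!any(vapply(nd$id, function(id) length(.oKids(nd, id)) >= 2L, logical(1))))
    return(NA_real_)
  mean(oracleSegmentLengths(tree))
}

oracleBifAngles <- function(tree, minOffset = 0.5) {
  nd <- .oClean(swcNodes(tree))
  rootId <- nd$id[nd$parent == -1L]
  dirFrom <- function(bId, kId) {
    acc <- .oDist(nd, bId, kId)
    cur <- kId
    while (acc < minOffset && length(.oKids(nd, cur)) == 1L) {
      nxt <- .oKids(nd, cur)
      acc <- acc + .oDist(nd, cur, nxt)
      cur <- nxt
    }
    v <- .oPos(nd, cur) - .oPos(nd, bId)
    v / sqrt(sum(v^2))
  }
  angs <- c()
  for (id in nd$id) {
    if (id == rootId) next
    kids <- .oKids(nd, id)
    if (length(kids) < 2L) next
    for (i in seq_len(length(kids) - 1L)) for (j in (i + 1):length(kids)) {
      d1 <- dirFrom(id, kids[i]); d2 <- dirFrom(id, kids[j])
      cs <- max(-1, min(1, sum(d1 * d2)))
      angs <- c(angs, acos(cs) * 180 / pi)
    }
  }
  angs
}

# convex hull by gift wrapping + triangle-fan area (independent of chull)
oracleCoverArea <- function(tree) {
  nd <- .oClean(swcNodes(tree))
  pts <- unique(cbind(nd$x, nd$y))
  if (nrow(pts) < 3L) return(0)
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- if (cur == 1L) 2L else 1L
    for (j in seq_len(nrow(pts))) {
      if (j == cur) next
      cr <- cross(pts[cur, ], pts[cand, ], pts[j, ])
      if (cand == cur || cr < 0 ||
          (cr == 0 && sum((pts[j, ] - pts[cur, ])^2) > sum((pts[cand, ] - pts[cur, ])^2)))
        cand <- j
    }
    if (cand == start) break
    hull <- c(hull, cand)
    if (length(hull) > nrow(pts)) stop("gift wrapping failed")
  }
  if (length(hull) < 3L) return(0)
  a <- 0
  for (i in 2:(length(hull) - 1L)) {
    a <- a + cross(pts[hull[1], ], pts[hull[i], ], pts[hull[i + 1], ])
  }
  abs(a) / 2
}
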