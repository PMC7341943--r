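# Fixture builders shared across test files.

# Y-shaped reference tree: root (0,0,0), trunk (0,10,0), daughters
# (6,18,0) and (-6,18,0); all three edges are exactly 10 um.
toyTree <- function() {
  nd <- data.frame(id = 1:4,
                   label = c("thallus", "rhizoid", "rhizoid", "rhizoid"),
                   x = c(0, 0, 6, -6), y = c(0, 10, 18, 18), z = 0,
                   radius = c(2.5, 0.25, 0.25, 0.25),
                   parent = c(-1L, 1L, 2L, 2L))
  TracedTree(nd, cellId = "toy")
}

rootOnlyTree <- function() {
  TracedTree(data.frame(id = 1L, label = "thallus", x = 0, y = 0, z = 0,
                        radius = 2.5, parent = -1L), cellId = "germling")
}

# unbranched filament of n nodes along +x
filamentTree <- function(n = 10, step = 2) {
  nd <- data.frame(id = seq_len(n),
                   label = c("thallus", rep("rhizoid", n - 1)),
                   x = (seq_len(n) - 1) * step, y = 0, z = 0,
                   radius = c(2.5, rep(0.25, n - 1)),
                   parent = c(-1L, seq_len(n - 1)))
  TracedTree(nd, cellId = "filament")
}

# random tree by preferential-free random attachment; positions continuous
# so no zero-length edges arise
randomTree <- function(n = 50, seed = 1, planar = FALSE) {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  radius <- c(2.5, runif(n - 1, 0.1, 1))
  parent <- c(-1L, rep(NA_integer_, n - 1))
  for (i in 2:n) {
    p <- sample.int(i - 1L, 1L)
    parent[i] <- p
    len <- runif(1, 0.5, 3)
    u <- rnorm(3)
    if (planar) u[3] <- 0
    u <- u / sqrt(sum(u^2))
    x[i] <- x[p] + len * u[1]
    y[i] <- y[p] + len * u[2]
    z[i] <- z[p] + len * u[3]
  }
  nd <- data.frame(id = seq_len(n), label = c("thallus", rep("rhizoid", n - 1)),
                   x = x, y = y, z = z, radius = radius, parent = parent)
  TracedTree(nd, cellId = sprintf("rand%d", seed))
}

# random strictly binary tree: every internal non-root node has 0 or 2 children
randomBinaryTree <- function(nInternal = 40, seed = 1) {
  set.seed(seed)
  nodes <- list(list(id = 1L, parent = -1L, pos = c(0, 0, 0)))
  leaves <- integer(0)
  # root gets exactly one trunk child
  nodes[[2]] <- list(id = 2L, parent = 1L,
                     pos = c(0, 0, 0) + rnorm(3))
  leaves <- 2L
  nid <- 2L
  for (i in seq_len(nInternal)) {
    # split a random leaf into two daughters
    l <- leaves[sample.int(length(leaves), 1L)]
    for (k in 1:2) {
      nid <- nid + 1L
      nodes[[nid]] <- list(id = nid, parent = l,
                           pos = nodes[[l]]$pos + rnorm(3))
      leaves <- c(leaves, nid)
    }
    leaves <- setdiff(leaves, l)
  }
  nd <- do.call(rbind, lapply(nodes, function(v)
    data.frame(id = v$id, parent = v$parent, x = v$pos[1], y = v$pos[2],
               z = v$pos[3])))
  nd$label <- c("thallus", rep("rhizoid", nrow(nd) - 1))
  nd$radius <- c(2.5, rep(0.25, nrow(nd) - 1))
  TracedTree(nd[, c("id", "label", "x", "y", "z", "radius", "parent")],
             cellId = sprintf("bin%d", seed))
}

# rigid rotation about z by `deg` degrees plus translation
transformTree <- function(tree, deg = 0, shift = c(0, 0, 0), scale = 1) {
  nd <- swcNodes(tree)
  a <- deg * pi / 180
  xy <- cbind(nd$x, nd$y) %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  nd$x <- xy[, 1] * scale + shift[1]
  nd$y <- xy[, 2] * scale + shift[2]
  nd$z <- nd$z * scale + shift[3]
  nd$radius <- nd$radius * if (scale != 1) scale else 1
  TracedTree(nd, cellId = cellId(tree), frameTime = frameTime(tree))
}

# filled disc at the centre with sparse single-pixel spokes to the edge:
# dense core, line-like periphery (fixture for local fractal analysis)
centreDenseGrid <- function(side = 400, discR = 60) {
  g <- matrix(FALSE, side, side)
  ctr <- side / 2
  rr <- matrix(seq_len(side), side, side)
  cc <- t(rr)
  g[(rr - ctr)^2 + (cc - ctr)^2 <= discR^2] <- TRUE
  for (a in seq(0, 2 * pi, length.out = 13)[-13]) {
    t <- seq(0, ctr - 12, by = 0.5)
    pr <- round(ctr + t * sin(a)); pc <- round(ctr + t * cos(a))
    ok <- pr >= 1 & pr <= side & pc >= 1 & pc <= side
    g[cbind(pr[ok], pc[ok])] <- TRUE
  }
  rasterGrid(g)
}
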