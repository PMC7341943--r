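## Internal indexed view of a TracedTree used by all morphometric code.
## Row-based: parentRow[i] is the row index of node i's parent (NA at root).

.treeIndex <- function(tree) {
  nd <- tree@nodes
  n <- nrow(nd)
  parentRow <- match(nd$parent, nd$id)
  rootRow <- which(nd$parent == -1L)
  nChild <- tabulate(parentRow[!is.na(parentRow)], nbins = n)
  pos <- cbind(nd$x, nd$y, nd$z)
  edgeChild <- which(!is.na(parentRow))            # rows having a parent
  ep <- parentRow[edgeChild]
  edgeLen <- sqrt(rowSums((pos[edgeChild, , drop = FALSE] -
                           pos[ep, , drop = FALSE])^2))
  list(nd = nd, n = n, pos = pos, parentRow = parentRow, rootRow = rootRow,
       nChild = nChild, edgeChild = edgeChild, edgeParent = ep,
       edgeLen = edgeLen)
}

## Drop degenerate zero-length edges: a child coinciding with its parent is
## removed and its own children re-attached to the parent. Rare in practice
## (dense traces can duplicate points); all metrics run on the cleaned tree.
.dropZeroEdges <- function(tree, tol = 0) {
  repeat {
    ix <- .treeIndex(tree)
    z <- ix$edgeChild[ix$edgeLen <= tol]
    if (length(z) == 0L) return(tree)
    nd <- ix$nd
    drop1 <- z[1]                    # one at a time keeps re-attachment simple
    pid <- nd$parent[drop1]
    nd$parent[nd$parent == nd$id[drop1]] <- pid
    tree@nodes <- nd[-drop1, , drop = FALSE]
    rownames(tree@nodes) <- NULL
  }
}

## O(1)-lookup child index: children of row v are
## ci$children[ci$start[v] + seq_len(nChild[v]) - 1L]
.childIndex <- function(ix) {
  po <- ix$parentRow[ix$edgeChild]
  o <- order(po)
  sortedChildren <- ix$edgeChild[o]
  sortedPar <- po[o]
  list(children = sortedChildren, start = match(seq_len(ix$n), sortedPar))
}

.kidsOf <- function(ci, v, nChild) {
  k <- nChild[v]
  if (k == 0L) return(integer(0))
  ci$children[ci$start[v] + seq_len(k) - 1L]
}

## Accumulate per-edge weights w (indexed by child row) from each node up to
## the root, by pointer doubling. Root is a zero-weight self-loop, so
## saturation past the root adds nothing.
.accumulateToRoot <- function(ix, w) {
  n <- ix$n
  acc <- w
  anc <- ix$parentRow
  anc[ix$rootRow] <- ix$rootRow
  for (i in seq_len(ceiling(log2(max(n, 2))) + 1L)) {
    acc <- acc + acc[anc]
    anc <- anc[anc]
  }
  acc
}

## Cumulative path length from the root to every node.
.rootPathLen <- function(ix) {
  w <- numeric(ix$n)
  w[ix$edgeChild] <- ix$edgeLen
  .accumulateToRoot(ix, w)
}

## Node depths (edge counts from the root).
.nodeDepths <- function(ix) {
  w <- numeric(ix$n)
  w[ix$edgeChild] <- 1
  as.integer(.accumulateToRoot(ix, w))
}

## Reverse-topological node order (children before parents).
.reverseTopo <- function(ix) {
  order(.nodeDepths(ix), decreasing = TRUE)
}

## Extremal path distance from every node down to a descendant tip.
## which = "min" or "max"; via[v] is the child row on the arg-extremal path.
.tipPathDist <- function(ix, which = c("min", "max")) {
  which <- match.arg(which)
  n <- ix$n
  useMin <- which == "min"
  dist <- ifelse(ix$nChild == 0L, 0, if (useMin) Inf else -Inf)
  via <- rep(NA_integer_, n)
  elen <- numeric(n)
  elen[ix$edgeChild] <- ix$edgeLen
  ord <- .reverseTopo(ix)
  pr <- ix$parentRow
  for (v in ord) {
    p <- pr[v]
    if (is.na(p)) next
    cand <- dist[v] + elen[v]
    if ((useMin && cand < dist[p]) || (!useMin && cand > dist[p])) {
      dist[p] <- cand
      via[p] <- v
    }
  }
  list(dist = dist, via = via)
}
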