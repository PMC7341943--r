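## Branch-event detection between consecutive frames and apical/lateral
## classification.
##
## A branch event is a node that carries >= 2 children in frame t+1 but
## fewer than two (or did not exist) in frame t. Its geometry is measured at
## first appearance:
##  * distance_to_tip — path distance from the insertion point to the tip of
##    its parent filament in the EARLIER frame (0 for a tip split);
##  * axis_angle — angle between the new branch's initial direction and the
##    parent filament's local axis, the direction of the ~2 um path segment
##    upstream of the insertion point.
## Apical branching forms at the tip parallel to the established axis;
## lateral branching inserts distally, founding a new axis. The operational
## thresholds (d_tip, theta_par) are free parameters and deliberately
## exposed.

#' Classify branch events as apical or lateral
#'
#' Apical iff `distanceToTip <= dTip` and `axisAngle <= thetaPar`; lateral
#' otherwise. The rule is threshold-monotone: raising either threshold can
#' only convert lateral calls to apical.
#'
#' @param distanceToTip path distance(s) to the parent filament tip, um.
#' @param axisAngle angle(s) to the parent filament axis, degrees.
#' @param dTip tip-proximity threshold in micrometres (default 1).
#' @param thetaPar parallelism threshold in degrees (default 30).
#' @return character vector, `"apical"` or `"lateral"`.
#' @export
classifyBranch <- function(distanceToTip, axisAngle, dTip = 1, thetaPar = 30) {
  ifelse(distanceToTip <= dTip & axisAngle <= thetaPar, "apical", "lateral")
}

## Greedy nearest-neighbour identity matching for series without stable ids.
## Returns for each node row of tree1 the matching node id in tree0 (NA if
## unmatched); ambiguous matches abort.
.matchNodeIds <- function(tree0, tree1, tol = 1) {
  p0 <- as.matrix(tree0@nodes[, c("x", "y", "z")])
  p1 <- as.matrix(tree1@nodes[, c("x", "y", "z")])
  n1 <- nrow(p1)
  out <- rep(NA_integer_, n1)
  claimed <- rep(FALSE, nrow(p0))
  for (i in seq_len(n1)) {
    d <- sqrt(colSums((t(p0) - p1[i, ])^2))
    j <- which.min(d)
    if (d[j] <= tol) {
      if (claimed[j])
        stop("ambiguous frame matching: two nodes map to the same predecessor ",
             "within ", tol, " um")
      claimed[j] <- TRUE
      out[i] <- tree0@nodes$id[j]
    }
  }
  out
}

#' Detect new branch events in a time series
#'
#' Compares consecutive frames of a [RhizoidTimeSeries-class] and reports
#' one event per branch point first appearing between the frames, with the
#' geometry needed for classification. When several daughters of a tip
#' split are new, the daughter best aligned with the parent axis is treated
#' as the continuation and the least aligned as the new branch.
#'
#' @param series a [RhizoidTimeSeries-class] with at least 2 frames.
#' @param dTip,thetaPar classification thresholds, see [classifyBranch()].
#' @param minOffset path offset (um) for direction chords.
#' @param axisWindow upstream path length (um) defining the local axis.
#' @param matchTol nearest-neighbour tolerance (um) used when node ids are
#'   not stable across frames.
#' @return data.frame with one row per event: `time` (hours, of the frame
#'   where the branch first appears), `parent_node_id`, `distance_to_tip`,
#'   `axis_angle`, `branch_class`. Zero rows if nothing branched.
#' @export
detectBranchEvents <- function(series, dTip = 1, thetaPar = 30,
                               minOffset = 0.5, axisWindow = 2, matchTol = 1) {
  stopifnot(is(series, "RhizoidTimeSeries"))
  fr <- series@frames
  if (length(fr) < 2L)
    return(data.frame(time = numeric(0), parent_node_id = integer(0),
                      distance_to_tip = numeric(0), axis_angle = numeric(0),
                      branch_class = character(0)))
  rows <- list()
  for (f in seq_len(length(fr) - 1L)) {
    t0 <- fr[[f]]; t1 <- fr[[f + 1L]]
    if (!series@idStable) {
      mapped <- .matchNodeIds(t0, t1, tol = matchTol)
      nd1 <- t1@nodes
      oldIds <- nd1$id
      newIds <- ifelse(is.na(mapped), max(t0@nodes$id) + seq_along(mapped), mapped)
      nd1$id <- as.integer(newIds)
      nd1$parent <- ifelse(nd1$parent == -1L, -1L,
                           as.integer(newIds[match(nd1$parent, oldIds)]))
      t1 <- TracedTree(nd1, cellId = t1@cellId, frameTime = t1@frameTime)
    }
    rows[[f]] <- .framePairEvents(t0, t1, minOffset, axisWindow)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev) || nrow(ev) == 0L)
    return(data.frame(time = numeric(0), parent_node_id = integer(0),
                      distance_to_tip = numeric(0), axis_angle = numeric(0),
                      branch_class = character(0)))
  ev$branch_class <- classifyBranch(ev$distance_to_tip, ev$axis_angle,
                                    dTip = dTip, thetaPar = thetaPar)
  rownames(ev) <- NULL
  ev
}

.framePairEvents <- function(t0, t1, minOffset, axisWindow) {
  ix0 <- .treeIndex(t0); ix1 <- .treeIndex(t1)
  ci1 <- .childIndex(ix1)
  ids0 <- ix0$nd$id
  present0 <- ix1$nd$id %in% ids0
  nChild0At <- function(id) {
    r <- match(id, ids0)
    if (is.na(r)) -1L else ix0$nChild[r]
  }
  elen1 <- numeric(ix1$n)
  elen1[ix1$edgeChild] <- ix1$edgeLen
  ## min path distance to a descendant tip, per node, in both frames
  tip0 <- .tipPathDist(ix0, "min")$dist
  tip1 <- .tipPathDist(ix1, "min")$dist
  cand <- which(ix1$nChild >= 2L & seq_len(ix1$n) != ix1$rootRow)
  cand <- cand[vapply(cand, function(b) nChild0At(ix1$nd$id[b]) < 2L, logical(1))]
  if (length(cand) == 0L) return(NULL)

  ## subtree contains an old node? computed per candidate by a bounded walk
  subtreeHasOld <- function(k) {
    stack <- k
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (present0[v]) return(TRUE)
      kk <- .kidsOf(ci1, v, ix1$nChild)
      stack <- c(stack, kk)
    }
    FALSE
  }
  chord1 <- function(b, k) {
    acc <- elen1[k]; cur <- k
    while (acc < minOffset && ix1$nChild[cur] == 1L) {
      nxt <- .kidsOf(ci1, cur, ix1$nChild)
      acc <- acc + elen1[nxt]
      cur <- nxt
    }
    v <- ix1$pos[cur, ] - ix1$pos[b, ]
    v / sqrt(sum(v^2))
  }
  out <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    b <- cand[i]
    kids <- .kidsOf(ci1, b, ix1$nChild)
    hasOld <- vapply(kids, subtreeHasOld, logical(1))
    ## local axis: chord over the upstream path at the insertion point
    up <- b; accUp <- 0
    while (!is.na(ix1$parentRow[up]) && accUp < axisWindow) {
      accUp <- accUp + elen1[up]
      up <- ix1$parentRow[up]
    }
    axis <- ix1$pos[b, ] - ix1$pos[up, ]
    nrm <- sqrt(sum(axis^2))
    axis <- if (nrm > 0) axis / nrm else c(1, 0, 0)
    angTo <- function(k) {
      d <- chord1(b, k)
      acos(max(-1, min(1, sum(d * axis)))) * 180 / pi
    }
    angles <- vapply(kids, angTo, numeric(1))
    if (any(hasOld)) {
      newKids <- kids[!hasOld]
      if (length(newKids) == 0L) next            # rewiring only, no new branch
      branchKid <- newKids[which.max(angles[!hasOld])]
    } else {
      ## tip split: most axis-aligned daughter continues the filament
      branchKid <- kids[which.max(angles)]
    }
    ## distance to the parent filament's tip in the earlier frame; when the
    ## filament grew entirely within the interval, fall back to the tip
    ## distance at first appearance
    bid <- ix1$nd$id[b]
    r0 <- match(bid, ids0)
    if (!is.na(r0)) {
      dtip <- tip0[r0]
    } else {
      acc <- 0; cur <- b
      repeat {
        kk <- .kidsOf(ci1, cur, ix1$nChild)
        if (cur == b) kk <- kk[kk != branchKid]
        kkOld <- kk[vapply(kk, subtreeHasOld, logical(1))]
        if (length(kkOld) == 0L) {
          dtip <- acc + if (length(kk)) min(elen1[kk] + tip1[kk]) else 0
          break
        }
        cur <- kkOld[1]
        acc <- acc + elen1[cur]
        if (present0[cur]) {
          dtip <- acc + tip0[match(ix1$nd$id[cur], ids0)]
          break
        }
      }
    }
    out[[i]] <- data.frame(time = t1@frameTime,
                           parent_node_id = bid,
                           distance_to_tip = dtip,
                           axis_angle = angles[kids == branchKid][1])
  }
  do.call(rbind, out)
}

#' Lateral versus apical branching fractions
#'
#' @param events data.frame with a `branch_class` column (from
#'   [detectBranchEvents()] or a simulator event log with classes
#'   `branch_lateral`/`branch_apical`).
#' @return list with `lateral_fraction`, `apical_fraction`, `n_lateral`,
#'   `n_apical`.
#' @export
branchRatio <- function(events) {
  cls <- events$branch_class
  if (is.null(cls)) cls <- sub("^branch_", "", events$type)
  cls <- sub("^branch_", "", cls)
  if (length(cls) == 0L) {
    warning("no branch events: fractions undefined")
    return(list(lateral_fraction = NA_real_, apical_fraction = NA_real_,
                n_lateral = 0L, n_apical = 0L))
  }
  nl <- sum(cls == "lateral"); na <- sum(cls == "apical")
  list(lateral_fraction = nl / (nl + na), apical_fraction = na / (nl + na),
       n_lateral = nl, n_apical = na)
}
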