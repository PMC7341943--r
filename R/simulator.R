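## Stochastic rhizoid growth simulator.
##
## Model: a thallus root puts out one germ-tube tip. The whole system shares
## a constant elongation budget V (um/h) split across active tips each step
## — total length therefore grows linearly in time while tips multiply,
## matching observed trajectories (a constant per-tip rate would give
## super-linear length growth). Branch events arrive as a Poisson process
## with constant per-system rate lambda (events/h) — tip production is
## likewise linear in time. Each event is lateral with probability p_lat
## (inserted at a length-uniform random point on the existing filament, at
## an angle drawn from a truncated normal about the local axis) and
## otherwise apical (the tip splits into daughters at +/- angle/2 about its
## heading). Tip headings random-walk with per-step s.d. kappa. Growth is
## planar (z = 0) by default, as cells develop along the dish bottom; a
## z-noise term turns on a 3-D mode. Node ids are stable across frames and
## a single seeded generator with fixed draw order (elongation noise in tip
## order, then branch arrivals) makes output bit-reproducible.

#' GrowthParams: simulator configuration
#'
#' @slot elongationBudget total system elongation V, um/h, shared across
#'   active tips.
#' @slot branchRate Poisson branch-event rate lambda, events/h per system.
#' @slot lateralProb probability that an event is lateral (vs apical).
#' @slot angleMu,angleSigma mean and s.d. (degrees) of the branch insertion
#'   angle, truncated to (0, 180).
#' @slot tipPersistence s.d. (degrees) of per-step tip heading noise.
#' @slot zSigma s.d. (degrees) of per-step elevation noise; 0 = planar.
#' @slot diameter rhizoid filament diameter, um.
#' @slot thallusRadius radius of the thallus sphere, um.
#' @slot dt integration step, hours.
#' @slot duration total simulated time, hours.
#' @slot frameInterval time between emitted SWC frames, hours.
#' @slot seed RNG seed.
#' @slot beadCentre,beadRadius optional substrate particle (chitin
#'   microbead): centre (um, length 3) and radius (um); `NA` disables it.
#' @slot contactTol contact distance beyond the bead surface, um.
#' @slot contactBranchRate lateral branch rate (events/h) on bead-contact
#'   filament (the feeding regime).
#' @slot contactSlowdown elongation weight of tips in bead contact
#'   (0..1; the searching/feeding trade-off).
#' @slot preset name of the preset this configuration came from.
#' @seealso [growthParams()], [rhizoidPreset()], [simulateRhizoid()]
#' @export
setClass("GrowthParams",
         slots = c(elongationBudget = "numeric", branchRate = "numeric",
                   lateralProb = "numeric", angleMu = "numeric",
                   angleSigma = "numeric", tipPersistence = "numeric",
                   zSigma = "numeric", diameter = "numeric",
                   thallusRadius = "numeric", dt = "numeric",
                   duration = "numeric", frameInterval = "numeric",
                   seed = "integer", beadCentre = "numeric",
                   beadRadius = "numeric", contactTol = "numeric",
                   contactBranchRate = "numeric", contactSlowdown = "numeric",
                   preset = "character"))

setValidity("GrowthParams", function(object) {
  bad <- character(0)
  pos1 <- function(v) length(v) == 1L && is.finite(v) && v > 0
  if (!pos1(object@elongationBudget)) bad <- c(bad, "elongationBudget (must be > 0)")
  if (!(length(object@branchRate) == 1L && is.finite(object@branchRate) &&
        object@branchRate >= 0)) bad <- c(bad, "branchRate (must be >= 0)")
  if (!(length(object@lateralProb) == 1L && object@lateralProb >= 0 &&
        object@lateralProb <= 1)) bad <- c(bad, "lateralProb (must be in [0,1])")
  if (!(length(object@angleMu) == 1L && object@angleMu > 0 &&
        object@angleMu < 180)) bad <- c(bad, "angleMu (must be in (0,180))")
  if (!(length(object@angleSigma) == 1L && object@angleSigma >= 0))
    bad <- c(bad, "angleSigma (must be >= 0)")
  if (!(length(object@tipPersistence) == 1L && object@tipPersistence >= 0))
    bad <- c(bad, "tipPersistence (must be >= 0)")
  if (!pos1(object@dt)) bad <- c(bad, "dt (must be > 0)")
  if (!pos1(object@duration)) bad <- c(bad, "duration (must be > 0)")
  if (!pos1(object@frameInterval)) bad <- c(bad, "frameInterval (must be > 0)")
  if (!pos1(object@diameter)) bad <- c(bad, "diameter (must be > 0)")
  if (!pos1(object@thallusRadius)) bad <- c(bad, "thallusRadius (must be > 0)")
  if (length(bad)) return(paste("invalid parameters:", paste(bad, collapse = "; ")))
  TRUE
})

setMethod("show", "GrowthParams", function(object) {
  cat(sprintf(paste0("GrowthParams [%s]: V = %g um/h, lambda = %g /h, ",
                     "p_lat = %g, angle %g +/- %g deg, %g h at dt = %g h, seed %d\n"),
              object@preset, object@elongationBudget, object@branchRate,
              object@lateralProb, object@angleMu, object@angleSigma,
              object@duration, object@dt, object@seed))
  if (!anyNA(object@beadCentre))
    cat(sprintf("  bead at (%g, %g, %g), radius %g um\n",
                object@beadCentre[1], object@beadCentre[2],
                object@beadCentre[3], object@beadRadius))
})

#' Construct simulator parameters
#'
#' Defaults are the carbon-replete configuration: the elongation budget and
#' branch rate equal the observed linear growth rates (110.8 um/h and 4.6
#' tips/h), the branch-angle distribution matches the observed local
#' bifurcation angle (81.4 +/- 6.3 degrees), and lateral branching
#' dominates (p_lat = 0.85).
#'
#' @param elongationBudget V, um/h.
#' @param branchRate lambda, events/h.
#' @param lateralProb lateral-event probability.
#' @param angleMu,angleSigma branch-angle distribution, degrees.
#' @param tipPersistence per-step heading noise s.d., degrees.
#' @param zSigma per-step elevation noise s.d., degrees (0 = planar).
#' @param diameter filament diameter, um.
#' @param thallusRadius thallus radius, um.
#' @param dt step, hours.
#' @param duration simulated time, hours.
#' @param frameInterval frame spacing, hours.
#' @param seed RNG seed.
#' @param beadCentre,beadRadius optional bead (um); `NA` = no bead.
#' @param contactTol contact tolerance beyond the bead surface, um.
#' @param contactBranchRate lateral rate on contact filament, events/h.
#' @param contactSlowdown elongation weight of contact tips.
#' @param preset preset label.
#' @return A validated [GrowthParams-class]; invalid values raise an error
#'   listing the offending fields.
#' @export
growthParams <- function(elongationBudget = 110.8, branchRate = 4.6,
                         lateralProb = 0.85, angleMu = 81.4, angleSigma = 6.3,
                         tipPersistence = 2, zSigma = 0, diameter = 0.5,
                         thallusRadius = 2.5, dt = 0.01, duration = 10,
                         frameInterval = 1, seed = 1L,
                         beadCentre = c(NA_real_, NA_real_, NA_real_),
                         beadRadius = NA_real_, contactTol = 1,
                         contactBranchRate = 12, contactSlowdown = 0.25,
                         preset = "custom") {
  new("GrowthParams", elongationBudget = elongationBudget,
      branchRate = branchRate, lateralProb = lateralProb, angleMu = angleMu,
      angleSigma = angleSigma, tipPersistence = tipPersistence,
      zSigma = zSigma, diameter = diameter, thallusRadius = thallusRadius,
      dt = dt, duration = duration, frameInterval = frameInterval,
      seed = as.integer(seed), beadCentre = as.numeric(beadCentre),
      beadRadius = as.numeric(beadRadius), contactTol = contactTol,
      contactBranchRate = contactBranchRate, contactSlowdown = contactSlowdown,
      preset = preset)
}

#' Phenotype presets for the growth simulator
#'
#' `"replete"` encodes growth under exogenous carbon: V = 110.8 um/h,
#' lambda = 4.6 events/h, p_lat = 0.85, branch angles 81.4 +/- 6.3 degrees.
#' `"starved"` encodes the carbon-starvation searching phenotype as
#' directional changes (graphical sources give no magnitudes, so these are
#' config-exposed): branch rate halved, insertion angles widened, the
#' elongation budget maintained — yielding longer, sparser, wider-angled
#' systems with greater reach. `"bead"` places a chitin microbead in an
#' otherwise carbon-free medium: filament in contact with the bead switches
#' to a densely branching, slow-extending feeding regime while
#' non-contact filament keeps the searching parameters.
#'
#' @param name one of `"replete"`, `"starved"`, `"bead"`.
#' @param ... overrides passed to [growthParams()] (e.g. `seed`,
#'   `duration`).
#' @return A [GrowthParams-class].
#' @export
rhizoidPreset <- function(name = c("replete", "starved", "bead"), ...) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("replete", "starved", "bead"))
    stop("unknown preset: ", paste(name, collapse = ", "),
         " (expected 'replete', 'starved' or 'bead')")
  base <- switch(name,
    replete = list(preset = "replete"),
    starved = list(branchRate = 2.3, angleMu = 95, preset = "starved"),
    bead = list(branchRate = 2.3, angleMu = 95,
                beadCentre = c(30, 0, 0), beadRadius = 8,
                preset = "bead"))
  do.call(growthParams, utils::modifyList(base, list(...)))
}

.rotZ <- function(v, ang) {
  ## rotate 3-vectors (rows) about the z axis
  ca <- cos(ang); sa <- sin(ang)
  cbind(ca * v[, 1] - sa * v[, 2], sa * v[, 1] + ca * v[, 2], v[, 3])
}

.truncNormAngle <- function(mu, sigma) {
  repeat {
    th <- stats::rnorm(1, mu, sigma)
    if (th > 0 && th < 180) return(th)
  }
}

#' Simulate stochastic rhizoid growth
#'
#' Runs the growth model described in [GrowthParams-class]/[rhizoidPreset()]
#' and returns the traced time series (with stable node ids) together with
#' the ground-truth event log. Identical parameters and seed give
#' bit-identical output.
#'
#' @param params a [GrowthParams-class].
#' @param cellId cell identifier for the emitted frames.
#' @return list with elements `series` (a [RhizoidTimeSeries-class]
#'   including the t = 0 germling frame), `events` (data.frame: `time`,
#'   `type` in `branch_lateral`/`branch_apical`, `branch_node`, `new_tip`,
#'   `angle`) and `params`.
#' @examples
#' sim <- simulateRhizoid(rhizoidPreset("replete", duration = 2, seed = 7))
#' sim$series
#' @export
simulateRhizoid <- function(params, cellId = sprintf("sim_s%d", params@seed)) {
  stopifnot(is(params, "GrowthParams"))
  methods::validObject(params)
  set.seed(params@seed)
  V <- params@elongationBudget; lam <- params@branchRate; dt <- params@dt
  kap <- params@tipPersistence * pi / 180
  zkap <- params@zSigma * pi / 180
  rRhiz <- params@diameter / 2
  eps <- 1e-6                         # branch insertion offset, um
  hasBead <- !anyNA(params@beadCentre) && is.finite(params@beadRadius)
  contactR <- if (hasBead) params@beadRadius + params@contactTol else NA_real_

  nsteps <- as.integer(round(params@duration / dt))
  frameEvery <- max(1L, as.integer(round(params@frameInterval / dt)))

  ## growing node store
  cap <- 8192L
  pos <- matrix(0, cap, 3); rad <- numeric(cap)
  par <- integer(cap); lab <- integer(cap)      # 1 = thallus, 3 = rhizoid
  n <- 0L
  ensure <- function(extra) {
    if (n + extra <= cap) return(invisible())
    newCap <- max(cap * 2L, n + extra)
    posN <- matrix(0, newCap, 3); posN[seq_len(n), ] <- pos[seq_len(n), ]
    pos <<- posN
    length(rad) <- newCap; length(par) <- newCap; length(lab) <- newCap
    rad <<- rad; par <<- par; lab <<- lab
    cap <<- newCap
  }
  addNode <- function(p, r, parent, label) {
    ensure(1L)
    n <<- n + 1L
    pos[n, ] <<- p; rad[n] <<- r; par[n] <<- parent; lab[n] <<- label
    n
  }

  ## initial state: thallus root + one germ-tube tip
  addNode(c(0, 0, 0), params@thallusRadius, -1L, 1L)
  addNode(c(eps, 0, 0), rRhiz, 1L, 3L)
  tipNode <- 2L
  tipPhi <- 0                          # azimuth, radians
  tipPsi <- 0                          # elevation, radians
  debt <- eps                          # offset length owed to the budget

  snapshot <- function(tHours) {
    nd <- data.frame(id = seq_len(n),
                     label = ifelse(lab[seq_len(n)] == 1L, "thallus", "rhizoid"),
                     x = pos[seq_len(n), 1], y = pos[seq_len(n), 2],
                     z = pos[seq_len(n), 3], radius = rad[seq_len(n)],
                     parent = par[seq_len(n)])
    TracedTree(nd, cellId = cellId, frameTime = tHours)
  }
  framesOut <- list(snapshot(0))
  evTime <- numeric(0); evType <- character(0)
  evBranch <- integer(0); evTip <- integer(0); evAngle <- numeric(0)

  currentEdgeLens <- function() {
    rows <- 2:n
    dp <- pos[rows, , drop = FALSE] - pos[par[rows], , drop = FALSE]
    sqrt(rowSums(dp^2))
  }
  insertLateral <- function(rows, lens, tNow) {
    ## rows: candidate child rows (edge = par[row] -> row), length-weighted
    if (length(rows) == 0L || sum(lens) <= 0) return(invisible(FALSE))
    e <- rows[sample.int(length(rows), 1L, prob = lens)]
    f <- stats::runif(1, 0.05, 0.95)
    pPar <- pos[par[e], ]; pChild <- pos[e, ]
    P <- pPar + f * (pChild - pPar)
    axisPhi <- atan2(pChild[2] - pPar[2], pChild[1] - pPar[1])
    th <- .truncNormAngle(params@angleMu, params@angleSigma)
    side <- if (stats::runif(1) < 0.5) -1 else 1
    phiNew <- axisPhi + side * th * pi / 180
    w <- addNode(P, rRhiz, par[e], 3L)
    par[e] <<- w
    dirNew <- c(cos(phiNew), sin(phiNew), 0)
    v <- addNode(P + eps * dirNew, rRhiz, w, 3L)
    debt <<- debt + eps
    tipNode <<- c(tipNode, v); tipPhi <<- c(tipPhi, phiNew)
    tipPsi <<- c(tipPsi, 0)
    evTime <<- c(evTime, tNow); evType <<- c(evType, "branch_lateral")
    evBranch <<- c(evBranch, w); evTip <<- c(evTip, v)
    evAngle <<- c(evAngle, th)
    invisible(TRUE)
  }

  for (step in seq_len(nsteps)) {
    tNow <- step * dt
    k <- length(tipNode)
    ## 1. elongation, heading noise drawn per tip in order
    tipPhi <- tipPhi + stats::rnorm(k, 0, kap)
    if (zkap > 0) tipPsi <- tipPsi + stats::rnorm(k, 0, zkap)
    budget <- V * dt
    pay <- min(debt, budget)
    budget <- budget - pay; debt <- debt - pay
    wgt <- rep(1, k)
    if (hasBead) {
      tp <- pos[tipNode, , drop = FALSE]
      dBead <- sqrt(colSums((t(tp) - params@beadCentre)^2))
      wgt[dBead <= contactR] <- params@contactSlowdown
    }
    stepLen <- budget * wgt / sum(wgt)
    dirs <- cbind(cos(tipPsi) * cos(tipPhi), cos(tipPsi) * sin(tipPhi),
                  sin(tipPsi))
    ensure(k)
    newRows <- n + seq_len(k)
    pos[newRows, ] <- pos[tipNode, , drop = FALSE] + stepLen * dirs
    rad[newRows] <- rRhiz
    par[newRows] <- tipNode
    lab[newRows] <- 3L
    n <- n + k
    tipNode <- newRows

    ## 2. branch arrivals (base process)
    m <- stats::rpois(1, lam * dt)
    if (m > 0) for (ev in seq_len(m)) {
      lens <- currentEdgeLens()
      rows <- 2:n
      if (hasBead) {
        ## searching regime branches only off non-contact filament
        mid <- (pos[rows, , drop = FALSE] + pos[par[rows], , drop = FALSE]) / 2
        free <- sqrt(colSums((t(mid) - params@beadCentre)^2)) > contactR
      } else free <- rep(TRUE, length(rows))
      if (stats::runif(1) < params@lateralProb) {
        insertLateral(rows[free], lens[free], tNow)
      } else {
        ## apical: a (non-contact) tip splits
        tipPool <- seq_along(tipNode)
        if (hasBead) {
          tp <- pos[tipNode, , drop = FALSE]
          freeTip <- sqrt(colSums((t(tp) - params@beadCentre)^2)) > contactR
          if (any(freeTip)) tipPool <- tipPool[freeTip]
        }
        j <- tipPool[sample.int(length(tipPool), 1L)]
        b <- tipNode[j]
        th <- .truncNormAngle(params@angleMu, params@angleSigma)
        half <- th / 2 * pi / 180
        phi1 <- tipPhi[j] + half; phi2 <- tipPhi[j] - half
        psi <- tipPsi[j]
        d1 <- c(cos(psi) * cos(phi1), cos(psi) * sin(phi1), sin(psi))
        d2 <- c(cos(psi) * cos(phi2), cos(psi) * sin(phi2), sin(psi))
        v1 <- addNode(pos[b, ] + eps * d1, rRhiz, b, 3L)
        v2 <- addNode(pos[b, ] + eps * d2, rRhiz, b, 3L)
        debt <- debt + 2 * eps
        tipNode[j] <- v1; tipPhi[j] <- phi1
        tipNode <- c(tipNode, v2); tipPhi <- c(tipPhi, phi2)
        tipPsi <- c(tipPsi, psi)
        evTime <- c(evTime, tNow); evType <- c(evType, "branch_apical")
        evBranch <- c(evBranch, b); evTip <- c(evTip, v1)
        evAngle <- c(evAngle, th)
      }
    }

    ## 3. feeding-regime arrivals on bead-contact filament
    if (hasBead) {
      mc <- stats::rpois(1, params@contactBranchRate * dt)
      if (mc > 0) for (ev in seq_len(mc)) {
        lens <- currentEdgeLens()
        rows <- 2:n
        mid <- (pos[rows, , drop = FALSE] + pos[par[rows], , drop = FALSE]) / 2
        inContact <- sqrt(colSums((t(mid) - params@beadCentre)^2)) <= contactR
        insertLateral(rows[inContact], lens[inContact], tNow)
      }
    }

    if (step %% frameEvery == 0L)
      framesOut[[length(framesOut) + 1L]] <- snapshot(tNow)
  }

  events <- data.frame(time = evTime, type = evType, branch_node = evBranch,
                       new_tip = evTip, angle = evAngle)
  list(series = rhizoidTimeSeries(framesOut, idStable = TRUE),
       events = events, params = params)
}

#' Split a rhizoid system into bead-contact and free subsystems
#'
#' Assigns every edge to the contact set iff its midpoint lies within
#' (bead radius + `contactTol`) of the bead centre, mirroring the
#' contact/non-contact comparison of particle-associated rhizoids.
#'
#' @param tree a [TracedTree-class].
#' @param beadCentre micrometre (x, y, z) of the bead centre.
#' @param beadRadius bead radius, um.
#' @param contactTol contact distance beyond the surface, um.
#' @return list with components `contact` and `free`, each a data.frame of
#'   edges (`child_id`, `parent_id`, `length`, `is_tip`).
#' @seealso [edgeSetSummary()]
#' @export
beadContactSplit <- function(tree, beadCentre, beadRadius, contactTol = 1) {
  stopifnot(is(tree, "TracedTree"))
  if (anyNA(beadCentre) || !is.finite(beadRadius))
    stop("no bead defined: beadCentre and beadRadius are required")
  ix <- .treeIndex(.dropZeroEdges(tree))
  mid <- (ix$pos[ix$edgeChild, , drop = FALSE] +
          ix$pos[ix$edgeParent, , drop = FALSE]) / 2
  inContact <- sqrt(colSums((t(mid) - beadCentre)^2)) <= beadRadius + contactTol
  isTip <- ix$nChild[ix$edgeChild] == 0L
  edges <- data.frame(child_id = ix$nd$id[ix$edgeChild],
                      parent_id = ix$nd$id[ix$edgeParent],
                      length = ix$edgeLen, is_tip = isTip)
  list(contact = edges[inContact, , drop = FALSE],
       free = edges[!inContact, , drop = FALSE])
}

#' Morphometric summary of an edge subset
#'
#' Total length, tip count and ratio-RGU of an edge set produced by
#' [beadContactSplit()] — tips are tree tips whose terminal edge belongs to
#' the set.
#'
#' @param edges data.frame of edges as returned in the components of
#'   [beadContactSplit()].
#' @return one-row data.frame: `total_length`, `n_tips`, `rgu_ratio`.
#' @export
edgeSetSummary <- function(edges) {
  nt <- sum(edges$is_tip)
  data.frame(total_length = sum(edges$length), n_tips = nt,
             rgu_ratio = if (nt > 0) sum(edges$length) / nt else NA_real_)
}
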