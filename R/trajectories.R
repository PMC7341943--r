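## Growth-trajectory fitting: per-frame metric time courses, per-cell OLS
## growth rates aggregated across cells, and per-compartment elongation
## rates at a fixed sampling interval.

.TIMECOURSE_METRICS <- c("total_length", "n_tips", "n_bifurcations",
                         "rgu_ratio", "rgu_segment", "surface_area",
                         "surface_area_total", "max_euclidean",
                         "mean_bif_angle", "cover_area")

.metricValue <- function(tree, metric) {
  switch(metric,
         total_length = totalLength(tree),
         n_tips = as.numeric(nTips(tree)),
         n_bifurcations = as.numeric(nBifurcations(tree)),
         rgu_ratio = suppressWarnings(rgu(tree, "ratio")),
         rgu_segment = suppressWarnings(rgu(tree, "segment")),
         surface_area = surfaceArea(tree, includeThallus = FALSE),
         surface_area_total = surfaceArea(tree, includeThallus = TRUE),
         max_euclidean = maxEuclidean(tree),
         mean_bif_angle = {
           a <- bifurcationAngles(tree)
           if (length(a)) mean(a) else NA_real_
         },
         cover_area = coverArea(tree),
         stop("unknown metric: ", metric, " (expected one of ",
              paste(.TIMECOURSE_METRICS, collapse = ", "), ")"))
}

#' Metric time course of a growing cell
#'
#' Evaluates one morphometric per frame of a time series.
#'
#' @param series a [RhizoidTimeSeries-class].
#' @param metric one of `total_length`, `n_tips`, `n_bifurcations`,
#'   `rgu_ratio`, `rgu_segment`, `surface_area`, `surface_area_total`,
#'   `max_euclidean`, `mean_bif_angle`, `cover_area`.
#' @return data.frame with columns `time` (hours) and `value`.
#' @export
metricTimecourse <- function(series, metric) {
  stopifnot(is(series, "RhizoidTimeSeries"))
  if (length(metric) != 1L || !metric %in% .TIMECOURSE_METRICS)
    stop("unknown metric: ", metric, " (expected one of ",
         paste(.TIMECOURSE_METRICS, collapse = ", "), ")")
  data.frame(time = frameTimes(series),
             value = vapply(series@frames, .metricValue, numeric(1),
                            metric = metric))
}

#' Fit per-cell growth rates and aggregate across cells
#'
#' Fits an ordinary-least-squares slope of metric versus time per cell and
#' reports the group mean, s.d. and s.e.m. across cells — the "n cells,
#' mean +/- s.e.m." presentation of biological replication (a pooled
#' regression would hide the between-cell variance). Cells with fewer than
#' 3 frames are skipped with a warning.
#'
#' @param cells a [RhizoidTimeSeries-class] or a list of them.
#' @param metric metric name as in [metricTimecourse()].
#' @return A [GrowthRateEstimate-class].
#' @export
fitGrowthRate <- function(cells, metric) {
  if (is(cells, "RhizoidTimeSeries")) cells <- list(cells)
  slopes <- numeric(0)
  for (s in cells) {
    if (nFrames(s) < 3L) {
      warning("cell '", cellId(s), "' skipped: fewer than 3 frames")
      next
    }
    tc <- metricTimecourse(s, metric)
    ok <- is.finite(tc$value)
    if (sum(ok) < 3L) {
      warning("cell '", cellId(s), "' skipped: fewer than 3 finite values")
      next
    }
    sl <- unname(stats::coef(stats::lm(value ~ time, data = tc[ok, ]))[2])
    slopes[cellId(s)] <- sl
  }
  if (length(slopes) == 0L) stop("no cell with enough frames to fit")
  new("GrowthRateEstimate", metric = metric, slopes = slopes,
      groupMean = mean(slopes),
      groupSd = if (length(slopes) > 1) stats::sd(slopes) else NA_real_,
      groupSem = if (length(slopes) > 1)
        stats::sd(slopes) / sqrt(length(slopes)) else NA_real_,
      nCells = length(slopes))
}

#' Per-compartment elongation rates
#'
#' Measures, for each terminal rhizoid compartment present at the start of
#' a sampling interval, the path length it adds over the interval (path
#' length along the filament, not Euclidean displacement, since filaments
#' curve), divided by the interval — the speed at which individual
#' compartments extend. The diameter-scaled rate divides by the compartment
#' diameter (2 x mean radius of the newly added path). Frames are paired
#' sequentially so that successive pairs are at least `interval` minutes
#' apart; node ids must be stable.
#'
#' @param series a [RhizoidTimeSeries-class] with stable ids.
#' @param interval sampling interval in minutes (default 30).
#' @return data.frame with one row per extending compartment and interval:
#'   `time0`, `time1` (hours), `tip_id` (tip node at the interval start),
#'   `rate` (um/min), `interval` (min), `diameter` (um), `scaled_rate`
#'   (1/min). Zero rows when no frames are `interval` apart.
#' @export
compartmentElongation <- function(series, interval = 30) {
  stopifnot(is(series, "RhizoidTimeSeries"))
  if (!series@idStable)
    stop("compartment elongation requires stable node ids across frames")
  tt <- frameTimes(series)
  empty <- data.frame(time0 = numeric(0), time1 = numeric(0),
                      tip_id = integer(0), rate = numeric(0),
                      interval = numeric(0), diameter = numeric(0),
                      scaled_rate = numeric(0))
  if (interval <= 0) stop("interval must be positive")
  ## sequential non-overlapping frame pairs >= interval apart
  pairs <- list()
  i <- 1L
  while (i < length(tt)) {
    j <- which((tt - tt[i]) * 60 >= interval - 1e-9)
    j <- j[j > i]
    if (length(j) == 0L) break
    pairs[[length(pairs) + 1L]] <- c(i, j[1])
    i <- j[1]
  }
  if (length(pairs) == 0L) return(empty)
  out <- list()
  for (pr in pairs) {
    t0 <- series@frames[[pr[1]]]; t1 <- series@frames[[pr[2]]]
    dMin <- (t1@frameTime - t0@frameTime) * 60
    ix0 <- .treeIndex(t0); ix1 <- .treeIndex(t1)
    tips0 <- ix0$nd$id[ix0$nChild == 0L & seq_len(ix0$n) != ix0$rootRow]
    present0 <- ix1$nd$id %in% ix0$nd$id
    ## walk up from every tip of the later frame to the first old node
    tips1 <- which(ix1$nChild == 0L & seq_len(ix1$n) != ix1$rootRow)
    elen1 <- numeric(ix1$n)
    elen1[ix1$edgeChild] <- ix1$edgeLen
    best <- list()
    for (tp in tips1) {
      cur <- tp; acc <- 0; radSum <- 0; nRad <- 0L
      while (!present0[cur] && !is.na(ix1$parentRow[cur])) {
        acc <- acc + elen1[cur]
        radSum <- radSum + ix1$nd$radius[cur]; nRad <- nRad + 1L
        cur <- ix1$parentRow[cur]
      }
      oid <- ix1$nd$id[cur]
      if (!(oid %in% tips0)) next              # grew from a new branch, skip
      radSum <- radSum + ix1$nd$radius[cur]; nRad <- nRad + 1L
      key <- as.character(oid)
      if (is.null(best[[key]]) || acc > best[[key]]$len)
        best[[key]] <- list(len = acc, dia = 2 * radSum / nRad)
    }
    if (length(best) == 0L) next
    oids <- as.integer(names(best))
    lens <- vapply(best, function(b) b$len, numeric(1))
    dias <- vapply(best, function(b) b$dia, numeric(1))
    rate <- lens / dMin
    out[[length(out) + 1L]] <- data.frame(
      time0 = t0@frameTime, time1 = t1@frameTime, tip_id = oids,
      rate = rate, interval = dMin, diameter = dias,
      scaled_rate = ifelse(dias > 0, rate / dias, NA_real_))
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
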