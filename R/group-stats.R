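## Group comparisons with the significance-star presentation used in
## morphometric figures.

#' Map p-values to significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns`
#' otherwise (strict thresholds: p = 0.05 is `ns`).
#'
#' @param p numeric vector of p-values.
#' @return character vector of `ns`/`*`/`**`/`***` (`NA` where p is `NA`).
#' @export
significanceStars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
                    ifelse(p[ok] < 0.01, "**",
                           ifelse(p[ok] < 0.05, "*", "ns")))
  out
}

#' Compare two groups of morphometric values
#'
#' Descriptives plus a two-sided test: Welch's t (default; the variances of
#' morphometrics routinely differ between conditions) or Mann-Whitney for
#' small-n robustness. With fewer than two values in a group only the
#' descriptives are returned.
#'
#' @param a,b numeric vectors of per-cell values.
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param metric optional metric label carried into the output.
#' @return one-row data.frame: `metric`, `test`, `mean_a`, `mean_b`,
#'   `sem_a`, `sem_b`, `n_a`, `n_b`, `statistic`, `p_value`, `stars`.
#' @export
compareGroups <- function(a, b, test = c("welch_t", "mann_whitney"),
                          metric = NA_character_) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  stat <- NA_real_; p <- NA_real_
  if (na >= 2 && nb >= 2) {
    res <- tryCatch(
      if (test == "welch_t") stats::t.test(a, b, var.equal = FALSE)
      else suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)),
      error = function(e) NULL)
    if (!is.null(res)) {
      stat <- unname(res$statistic)
      p <- res$p.value
    }
  }
  data.frame(metric = metric, test = test,
             mean_a = if (na) mean(a) else NA_real_,
             mean_b = if (nb) mean(b) else NA_real_,
             sem_a = sem(a), sem_b = sem(b), n_a = na, n_b = nb,
             statistic = stat, p_value = p,
             stars = significanceStars(p))
}

#' Metric-by-metric contrast of two sets of morphometry records
#'
#' One [compareGroups()] row per requested metric, e.g. contrasting
#' bead-contact against free rhizoid subsystems or starved against replete
#' cells. No multiple-testing correction is applied by default (stars are
#' reported per metric as in the source presentation); set
#' `adjust = "BH"` for Benjamini-Hochberg-adjusted p-values and stars.
#'
#' @param recordsA,recordsB data.frames of morphometry records
#'   (one row per cell, columns as [morphometry()]).
#' @param metrics character vector of metric columns to compare.
#' @param test see [compareGroups()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per metric.
#' @export
pairedRhizoidContrast <- function(recordsA, recordsB, metrics,
                                  test = c("welch_t", "mann_whitney"),
                                  adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (length(metrics) == 0L)
    return(data.frame(metric = character(0), test = character(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      sem_a = numeric(0), sem_b = numeric(0),
                      n_a = integer(0), n_b = integer(0),
                      statistic = numeric(0), p_value = numeric(0),
                      stars = character(0)))
  bad <- setdiff(metrics, intersect(names(recordsA), names(recordsB)))
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "))
  rows <- lapply(metrics, function(m)
    compareGroups(recordsA[[m]], recordsB[[m]], test = test, metric = m))
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
    out$stars <- significanceStars(out$p_value)
  }
  rownames(out) <- NULL
  out
}
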