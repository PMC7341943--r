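## Accessor generics. Slot access outside the package should go through these.

#' Accessors for rhizomorph core classes
#'
#' `swcNodes()` returns the node table of a [TracedTree-class];
#' `cellId()` and `frameTime()` its identifiers; `frames()`,
#' `frameTimes()` and `nFrames()` unpack a [RhizoidTimeSeries-class].
#'
#' @param x a `TracedTree` or `RhizoidTimeSeries`.
#' @return `swcNodes()`: data.frame; `frames()`: list of `TracedTree`;
#'   `frameTimes()`: numeric hours; the rest scalars.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("swcNodes", function(x) standardGeneric("swcNodes"))
#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("swcNodes", "TracedTree", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("cellId", "TracedTree", function(x) x@cellId)
#' @rdname accessors
#' @export
setMethod("frameTime", "TracedTree", function(x) x@frameTime)
#' @rdname accessors
#' @export
setMethod("frames", "RhizoidTimeSeries", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frameTimes", "RhizoidTimeSeries", function(x)
  vapply(x@frames, function(f) f@frameTime, numeric(1)))
#' @rdname accessors
#' @export
setMethod("nFrames", "RhizoidTimeSeries", function(x) length(x@frames))
#' @rdname accessors
#' @export
setMethod("cellId", "RhizoidTimeSeries", function(x) x@frames[[1]]@cellId)
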