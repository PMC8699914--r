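#' WeightedSupport: block-weighted allele support per cell
#'
#' Produced by \code{\link{mergeReads}}. For every (marker, haplotype) cell,
#' \code{wRef}/\code{wAlt} hold the weighted read counts supporting each
#' allele: the haplotype's own reads times the self-weight plus the unweighted
#' reads of all block neighbors. \code{wHaps} is the weighted haplotype count
#' (self-weight + number of neighbors), the denominator of the read-depth
#' estimate. \code{covered} marks cells lying in at least one block; uncovered
#' cells still carry their own self-weighted reads but get no depth estimate.
#'
#' @param x a \code{WeightedSupport}.
#' @aliases wRef wAlt wHaps covered
#' @export
setClass("WeightedSupport", representation(
  wRef = "matrix", wAlt = "matrix", nNeighbors = "matrix",
  coveredCells = "matrix", selfWeight = "numeric", markers = "data.frame"))

.validWeightedSupport <- function(object) {
  d <- dim(object@wRef)
  if (!identical(d, dim(object@wAlt)) || !identical(d, dim(object@nNeighbors)) ||
      !identical(d, dim(object@coveredCells)))
    return("all matrices must share dimensions")
  if (any(object@wRef < 0) || any(object@wAlt < 0))
    return("weighted read counts must be non-negative")
  if (object@selfWeight < 1) return("selfWeight must be >= 1")
  TRUE
}
setValidity("WeightedSupport", .validWeightedSupport)

#' @rdname WeightedSupport-class
#' @export
setMethod("wRef", "WeightedSupport", function(x) x@wRef)

#' @rdname WeightedSupport-class
#' @export
setMethod("wAlt", "WeightedSupport", function(x) x@wAlt)

#' @rdname WeightedSupport-class
#' @export
setMethod("wHaps", "WeightedSupport", function(x) x@selfWeight + x@nNeighbors)

#' @rdname WeightedSupport-class
#' @export
setMethod("covered", "WeightedSupport", function(x) x@coveredCells)

setMethod("show", "WeightedSupport", function(object) {
  cat(sprintf(
    "WeightedSupport: %d markers x %d haplotypes (self-weight %g, %.1f%% covered)\n",
    nrow(object@wRef), ncol(object@wRef), object@selfWeight,
    100 * mean(object@coveredCells)))
  invisible(NULL)
})

#' DepthTrack: estimated local read-depth per cell
#'
#' Produced by \code{\link{estimateDepth}}: weighted reads divided by the
#' weighted haplotype count, \code{NA} for cells covered by no block (depth
#' cannot be estimated there). \code{haplotypeMeans} are per-haplotype means
#' over covered cells.
#'
#' @param x a \code{DepthTrack}.
#' @aliases depthMatrix haplotypeMeans
#' @export
setClass("DepthTrack", representation(
  depth = "matrix", hapMeans = "numeric", markers = "data.frame"))

.validDepthTrack <- function(object) {
  if (any(object@depth < 0, na.rm = TRUE))
    return("depth must be non-negative where estimated")
  if (length(object@hapMeans) != ncol(object@depth))
    return("one haplotype mean per column required")
  TRUE
}
setValidity("DepthTrack", .validDepthTrack)

#' @rdname DepthTrack-class
#' @export
setMethod("depthMatrix", "DepthTrack", function(x) x@depth)

#' @rdname DepthTrack-class
#' @export
setMethod("haplotypeMeans", "DepthTrack", function(x) x@hapMeans)

#' @rdname DepthTrack-class
#' @export
setMethod("markerInfo", "DepthTrack", function(x) x@markers)

setMethod("show", "DepthTrack", function(object) {
  cat(sprintf(
    "DepthTrack: %d markers x %d haplotypes; mean %.3fX over covered cells (%.1f%% gaps)\n",
    nrow(object@depth), ncol(object@depth),
    mean(object@depth, na.rm = TRUE), 100 * mean(is.na(object@depth))))
  invisible(NULL)
})
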