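#' @import methods
#' @importFrom stats rbinom rnorm rpois runif var cor pt sd setNames
#' @importFrom utils read.table write.table head
#' @importFrom graphics hist
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData rowRanges
NULL

#' @rdname HaplotypePanel-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("refReads", function(x) standardGeneric("refReads"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("altReads", function(x) standardGeneric("altReads"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("haplotypeIds", function(x) standardGeneric("haplotypeIds"))

#' @rdname BlockLibrary-class
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname WeightedSupport-class
#' @export
setGeneric("wRef", function(x) standardGeneric("wRef"))

#' @rdname WeightedSupport-class
#' @export
setGeneric("wAlt", function(x) standardGeneric("wAlt"))

#' @rdname WeightedSupport-class
#' @export
setGeneric("wHaps", function(x) standardGeneric("wHaps"))

#' @rdname WeightedSupport-class
#' @export
setGeneric("covered", function(x) standardGeneric("covered"))

#' @rdname DepthTrack-class
#' @export
setGeneric("depthMatrix", function(x) standardGeneric("depthMatrix"))

#' @rdname DepthTrack-class
#' @export
setGeneric("haplotypeMeans", function(x) standardGeneric("haplotypeMeans"))
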