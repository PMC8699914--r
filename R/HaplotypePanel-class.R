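#' HaplotypePanel: genotype calls with per-allele read counts
#'
#' A \code{HaplotypePanel} holds a biallelic variant panel for a set of
#' haplotypes (for fully inbred lines: one haplotype per line). It extends
#' \linkS4class{RangedSummarizedExperiment} with three assays of identical
#' dimension (markers in rows, haplotypes in columns):
#' \describe{
#'   \item{\code{calls}}{integer; \code{0} = REF, \code{1} = ALT,
#'     \code{NA} = missing.}
#'   \item{\code{refReads}, \code{altReads}}{non-negative integer read counts
#'     supporting each allele, as reported by the upstream variant caller
#'     (e.g. the \code{AD} field of a VCF).}
#' }
#' Row metadata carries the marker annotation: \code{ref}/\code{alt} allele
#' strings, an optional \code{markerId}, a logical \code{isSnp} flag
#' (\code{FALSE} for appended CNV pseudo-markers), and \code{chromIndex}, the
#' 0-based index of each SNP marker within its chromosome. \code{chromIndex}
#' is assigned at construction and preserved when the panel is subset, so a
#' \linkS4class{BlockLibrary} expressed in these indices remains valid after
#' marker filtering.
#'
#' A cell may carry a call with zero reads (the source file asserted one);
#' read merging uses reads only, so such calls contribute nothing there but
#' are re-inserted by \code{\link{finalizeCalls}}.
#'
#' @param calls integer matrix (markers x haplotypes) with values 0/1/NA.
#' @param refReads,altReads non-negative integer matrices, same dimension as
#'   \code{calls}; default all-zero (array-derived panels carry no reads).
#' @param markers \code{data.frame} with columns \code{chrom}, \code{pos}
#'   (1-based bp), \code{ref}, \code{alt}, and optionally \code{end},
#'   \code{markerId}, \code{isSnp}.
#' @param haplotypeIds character vector of column identifiers.
#' @param x a \code{HaplotypePanel}.
#'
#' @return \code{HaplotypePanel()} returns a validated object. Accessors
#'   \code{calls}, \code{refReads}, \code{altReads} return matrices;
#'   \code{markerInfo} the marker annotation \code{data.frame};
#'   \code{haplotypeIds} the column identifiers.
#'
#' @examples
#' toy <- toyExample()
#' toy$panel
#' calls(toy$panel)[1:3, ]
#'
#' @aliases calls refReads altReads markerInfo haplotypeIds
#' @export
setClass("HaplotypePanel", contains = "RangedSummarizedExperiment")

.validHaplotypePanel <- function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("calls", "refReads", "altReads")
  if (!all(need %in% an))
    return(paste("assays must include", paste(need, collapse = ", ")))
  cl <- SummarizedExperiment::assay(object, "calls")
  rr <- SummarizedExperiment::assay(object, "refReads")
  ar <- SummarizedExperiment::assay(object, "altReads")
  if (!all(cl %in% c(0L, 1L, NA)))
    msg <- c(msg, "calls must be 0 (REF), 1 (ALT) or NA (missing)")
  if (anyNA(rr) || anyNA(ar) || any(rr < 0) || any(ar < 0))
    msg <- c(msg, "read counts must be non-negative and non-missing")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("ref", "alt", "isSnp", "chromIndex") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry ref, alt, isSnp, chromIndex")
  else {
    chrom <- as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(object)))
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(object))
    snp <- rd$isSnp
    for (ch in unique(chrom[snp])) {
      p <- pos[snp & chrom == ch]
      if (any(diff(p) <= 0)) {
        msg <- c(msg, sprintf(
          "SNP positions must be strictly increasing on chromosome %s", ch))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("HaplotypePanel", .validHaplotypePanel)

#' @rdname HaplotypePanel-class
#' @export
HaplotypePanel <- function(calls, refReads = NULL, altReads = NULL, markers,
                           haplotypeIds = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(refReads))
    refReads <- matrix(0L, nrow(calls), ncol(calls))
  if (is.null(altReads))
    altReads <- matrix(0L, nrow(calls), ncol(calls))
  refReads <- as.matrix(refReads); storage.mode(refReads) <- "integer"
  altReads <- as.matrix(altReads); storage.mode(altReads) <- "integer"
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "ref", "alt") %in% colnames(markers)),
            nrow(markers) == nrow(calls))
  if (is.null(haplotypeIds))
    haplotypeIds <- sprintf("H%d", seq_len(ncol(calls)))
  if (is.null(markers$end)) markers$end <- markers$pos
  if (is.null(markers$isSnp)) markers$isSnp <- TRUE
  if (is.null(markers$markerId))
    markers$markerId <- sprintf("%s_%d", markers$chrom, markers$pos)
  chromIndex <- rep(NA_integer_, nrow(markers))
  for (ch in unique(markers$chrom[markers$isSnp])) {
    i <- which(markers$isSnp & markers$chrom == ch)
    chromIndex[i] <- seq_along(i) - 1L
  }
  gr <- GenomicRanges::GRanges(
    seqnames = markers$chrom,
    ranges = IRanges::IRanges(start = markers$pos, end = markers$end),
    ref = as.character(markers$ref), alt = as.character(markers$alt),
    markerId = as.character(markers$markerId),
    isSnp = markers$isSnp, chromIndex = chromIndex)
  dimnames(calls) <- list(markers$markerId, haplotypeIds)
  dimnames(refReads) <- dimnames(calls)
  dimnames(altReads) <- dimnames(calls)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls, refReads = refReads, altReads = altReads),
    rowRanges = gr,
    colData = S4Vectors::DataFrame(row.names = haplotypeIds))
  new("HaplotypePanel", se)
}

#' @rdname HaplotypePanel-class
#' @export
setMethod("calls", "HaplotypePanel", function(x)
  SummarizedExperiment::assay(x, "calls"))

#' @rdname HaplotypePanel-class
#' @export
setMethod("refReads", "HaplotypePanel", function(x)
  SummarizedExperiment::assay(x, "refReads"))

#' @rdname HaplotypePanel-class
#' @export
setMethod("altReads", "HaplotypePanel", function(x)
  SummarizedExperiment::assay(x, "altReads"))

#' @rdname HaplotypePanel-class
#' @export
setMethod("markerInfo", "HaplotypePanel", function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    ref = gr$ref, alt = gr$alt, markerId = gr$markerId,
    isSnp = gr$isSnp, chromIndex = gr$chromIndex,
    stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname HaplotypePanel-class
#' @export
setMethod("haplotypeIds", "HaplotypePanel", function(x) colnames(x))

setMethod("show", "HaplotypePanel", function(object) {
  cl <- calls(object)
  cat(sprintf(
    "HaplotypePanel: %d markers x %d haplotypes (%.1f%% missing calls)\n",
    nrow(object), ncol(object), 100 * mean(is.na(cl))))
  info <- markerInfo(object)
  cat(sprintf("  chromosomes: %s; %d non-SNP pseudo-markers\n",
              paste(unique(info$chrom), collapse = ", "),
              sum(!info$isSnp)))
  invisible(NULL)
})

# replace the calls assay, keeping everything else
.setCalls <- function(panel, newCalls) {
  storage.mode(newCalls) <- "integer"
  dimnames(newCalls) <- dimnames(calls(panel))
  SummarizedExperiment::assay(panel, "calls") <- newCalls
  panel
}
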