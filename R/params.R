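#' Parameters of the block-based calling step
#'
#' @param selfWeight weight applied to a haplotype's own reads when merging
#'   with block neighbors (each neighbor counts once). The default 5 biases
#'   consensus calls toward the line itself so that recent or rare variation
#'   is not swamped by the block.
#' @param minShare minimum fraction of weighted reads that must support one
#'   allele for a consensus call (a share exactly at the threshold counts,
#'   i.e. "at least"). Must exceed 0.5 so calls are unambiguous.
#' @param minDepthFrac markers whose mean estimated depth over covered cells
#'   falls strictly below this fraction of the overall pre-filter mean are
#'   dropped.
#' @param maxMissing markers with strictly more than this fraction of missing
#'   calls are dropped.
#' @return a validated named list.
#' @export
hbParams <- function(selfWeight = 5, minShare = 0.8,
                     minDepthFrac = 0.5, maxMissing = 0.5) {
  stopifnot(selfWeight >= 1, minShare > 0.5, minShare <= 1,
            minDepthFrac >= 0, maxMissing >= 0, maxMissing <= 1)
  list(selfWeight = selfWeight, minShare = minShare,
       minDepthFrac = minDepthFrac, maxMissing = maxMissing)
}

#' Parameters of read-depth smoothing and CNV classification
#'
#' @param bandwidthBp standard deviation, in base pairs, of the Gaussian
#'   kernel of the Nadaraya-Watson depth smoother (default 0.25 Mb). Smaller
#'   values target shorter CNV segments.
#' @param dupRatio smoothed individual depth strictly above this multiple of
#'   the population average is classified as a duplication.
#' @param delRatio smoothed depth strictly below this multiple is classified
#'   as a deletion.
#' @param highDepth threshold on per-haplotype standardized smoothed depth
#'   for \code{\link{highDepthFlags}}.
#' @param standardize divide the individual track by its haplotype's
#'   genome-wide mean and the population track by the all-haplotype mean
#'   before forming ratios. Recommended outside toy settings: the individual
#'   track is self-weighted while the population average is raw, so absolute
#'   ratios are inflated.
#' @return a validated named list.
#' @export
cnvParams <- function(bandwidthBp = 250000, dupRatio = 1.3, delRatio = 0.7,
                      highDepth = 1.5, standardize = FALSE) {
  stopifnot(bandwidthBp > 0, delRatio < 1, dupRatio > 1)
  list(bandwidthBp = bandwidthBp, dupRatio = dupRatio, delRatio = delRatio,
       highDepth = highDepth, standardize = standardize)
}

#' Marker hygiene options applied at VCF ingest
#'
#' @param hetFractionMax markers whose fraction of heterozygous genotypes
#'   among non-missing genotypes exceeds this value are dropped (fully
#'   homozygous material should show essentially no heterozygous calls).
#' @param dropFixed drop markers where no called cell carries the minor
#'   allele.
#' @param maxAlleles maximum number of alleles (REF + ALT) per marker; more
#'   alternates cause the marker to be dropped with a warning.
#' @return a validated named list.
#' @export
ingestOptions <- function(hetFractionMax = 0.01, dropFixed = TRUE,
                          maxAlleles = 2) {
  stopifnot(hetFractionMax >= 0, hetFractionMax <= 1, maxAlleles >= 2)
  list(hetFractionMax = hetFractionMax, dropFixed = dropFixed,
       maxAlleles = as.integer(maxAlleles))
}

#' Parameters of GWAS region joining and classification
#'
#' @param joinDistBp significant markers at most this far apart chain into
#'   one region (default 1 Mb).
#' @param hitDistBp a region is a true positive if a simulated QTL lies
#'   within this distance of the region's bp interval (default 1 Mb).
#' @param pThreshold significance cutoff applied to per-marker p-values.
#' @return a validated named list.
#' @export
gwasEvalParams <- function(joinDistBp = 1e6, hitDistBp = 1e6,
                           pThreshold = 1e-5) {
  stopifnot(joinDistBp > 0, hitDistBp > 0, pThreshold > 0, pThreshold <= 1)
  list(joinDistBp = joinDistBp, hitDistBp = hitDistBp,
       pThreshold = pThreshold)
}
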