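#' Merge reads across block neighbors
#'
#' For every (marker, haplotype) cell the weighted allele support is
#' \deqn{w_a = s \cdot r_a(h) + \sum_{g \in N(h,m)} r_a(g)}
#' where \eqn{s} is the self-weight, \eqn{r_a} the raw read count for allele
#' \eqn{a} and \eqn{N(h,m)} the union of members of all blocks containing
#' \eqn{h} and covering \eqn{m} (minus \eqn{h}). Only raw reads participate:
#' a call asserted without reads (e.g. imputed upstream) contributes nothing.
#' The weighted haplotype count is \eqn{s + |N(h,m)|}; cells in no block keep
#' their own self-weighted reads with denominator \eqn{s}, but are marked
#' uncovered.
#'
#' @param panel a \code{\link{HaplotypePanel}}.
#' @param lib a \code{\link{BlockLibrary}} with indices within the panel's
#'   per-chromosome marker range.
#' @param params list from \code{\link{hbParams}}.
#' @return a \code{\linkS4class{WeightedSupport}}.
#' @examples
#' toy <- toyExample()
#' s <- mergeReads(toy$panel, toy$library)
#' wAlt(s)["chr1_500", "H1"]  # 5: own ALT read counted five times
#' wRef(s)["chr1_500", "H1"]  # 1: H2's REF read
#' @export
mergeReads <- function(panel, lib, params = hbParams()) {
  validateLibrary(lib, panel)
  R <- refReads(panel)
  A <- altReads(panel)
  info <- markerInfo(panel)
  haps <- haplotypeIds(panel)
  sw <- params$selfWeight
  wR <- sw * R
  wA <- sw * A
  nN <- matrix(0L, nrow(R), ncol(R), dimnames = dimnames(R))
  cov <- matrix(FALSE, nrow(R), ncol(R), dimnames = dimnames(R))
  for (ch in unique(info$chrom[info$isSnp])) {
    rows <- which(info$isSnp & info$chrom == ch)  # ordered by chromIndex
    for (seg in .blockSegments(lib, ch, length(rows))) {
      if (!length(seg$blockIdx)) next
      nm <- .neighborMatrix(lib, seg$blockIdx, haps)
      sr <- rows[(seg$start + 1L):seg$end]
      N <- nm$neighbors * 1
      wR[sr, ] <- wR[sr, ] + R[sr, , drop = FALSE] %*% t(N)
      wA[sr, ] <- wA[sr, ] + A[sr, , drop = FALSE] %*% t(N)
      nN[sr, ] <- nN[sr, ] + matrix(rowSums(N), length(sr), length(haps),
                                    byrow = TRUE)
      cov[sr, nm$covered] <- TRUE
    }
  }
  new("WeightedSupport", wRef = wR, wAlt = wA, nNeighbors = nN,
      coveredCells = cov, selfWeight = sw, markers = info)
}

#' Consensus genotype calls from weighted support
#'
#' A cell is called to allele \eqn{a} iff its weighted share
#' \eqn{w_a / (w_{ref} + w_{alt})} is at least \code{minShare} and any reads
#' are present; otherwise it stays missing. With \code{minShare > 0.5} at
#' most one allele can qualify.
#'
#' @param s a \code{\linkS4class{WeightedSupport}}.
#' @param params list from \code{\link{hbParams}}.
#' @return integer call matrix (0/1/\code{NA}), markers x haplotypes.
#' @export
callFromSupport <- function(s, params = hbParams()) {
  tot <- s@wRef + s@wAlt
  out <- matrix(NA_integer_, nrow(tot), ncol(tot), dimnames = dimnames(tot))
  pos <- tot > 0
  out[pos & s@wAlt / tot >= params$minShare] <- 1L
  out[pos & s@wRef / tot >= params$minShare] <- 0L
  out
}

#' Insert consensus calls into the raw panel
#'
#' Per cell: a consensus call takes precedence (it may overwrite a
#' conflicting raw call when many block members carry the other variant —
#' the mechanism by which upstream calling errors are corrected); otherwise
#' an existing raw call is kept (rare variants with read support but no
#' consensus survive); otherwise the cell stays missing. Never converts a
#' called cell to missing.
#'
#' @param hbCalls call matrix from \code{\link{callFromSupport}}.
#' @param rawPanel the raw \code{\link{HaplotypePanel}} (same shape).
#' @return list with \code{calls} (final matrix) and \code{provenance}
#'   (character matrix: \code{"RAW_CALLED"} where the raw panel had a call,
#'   whether or not overwritten; \code{"HB_CALLED"} where first called by
#'   consensus; \code{"MISSING"} otherwise).
#' @export
finalizeCalls <- function(hbCalls, rawPanel) {
  raw <- calls(rawPanel)
  stopifnot(identical(dim(hbCalls), dim(raw)))
  out <- ifelse(!is.na(hbCalls), hbCalls, raw)
  storage.mode(out) <- "integer"
  prov <- matrix("MISSING", nrow(raw), ncol(raw), dimnames = dimnames(raw))
  prov[!is.na(hbCalls) & is.na(raw)] <- "HB_CALLED"
  prov[!is.na(raw)] <- "RAW_CALLED"
  list(calls = out, provenance = prov)
}

#' Estimated read-depth per cell
#'
#' Depth is weighted reads over the weighted haplotype count,
#' \eqn{(w_{ref}+w_{alt}) / (s + |N|)}, where the cell is covered by at least
#' one block; \code{NA} (not covered) elsewhere. The reported values include
#' the self-weighting of the line's own reads.
#'
#' @param s a \code{\linkS4class{WeightedSupport}}.
#' @return a \code{\linkS4class{DepthTrack}}.
#' @examples
#' toy <- toyExample()
#' d <- depthMatrix(estimateDepth(mergeReads(toy$panel, toy$library)))
#' d["chr1_400", ]  # 2/7, 6/7, 6/7, 0, 0
#' @export
estimateDepth <- function(s) {
  depth <- (s@wRef + s@wAlt) / (s@selfWeight + s@nNeighbors)
  depth[!s@coveredCells] <- NA_real_
  hm <- colMeans(depth, na.rm = TRUE)
  hm[is.nan(hm)] <- NA_real_
  new("DepthTrack", depth = depth, hapMeans = hm, markers = s@markers)
}

#' Marker quality filters on depth and missingness
#'
#' A marker is dropped when its mean estimated depth over covered cells is
#' strictly below \code{minDepthFrac} times the overall mean depth (over all
#' covered cells of all markers, before any filtering), or when its fraction
#' of missing calls is strictly above \code{maxMissing}. Both filters are
#' evaluated against the pre-filter overall mean in one pass, so their order
#' cannot matter. Markers with no covered cell have no depth estimate and
#' are exempt from the depth filter.
#'
#' @param callsMat call matrix (markers x haplotypes).
#' @param depth a \code{\linkS4class{DepthTrack}} of the same shape.
#' @param params list from \code{\link{hbParams}}.
#' @return list with \code{keep} (retained marker row indices, in order) and
#'   \code{dropLog} (\code{data.frame} of dropped rows with reason codes
#'   \code{"LOW_DEPTH"} / \code{"HIGH_MISSING"}).
#' @export
filterMarkers <- function(callsMat, depth, params = hbParams()) {
  dm <- depthMatrix(depth)
  stopifnot(identical(dim(callsMat), dim(dm)))
  nCov <- rowSums(!is.na(dm))
  markerMean <- rowMeans(dm, na.rm = TRUE)
  overall <- mean(dm, na.rm = TRUE)
  lowDepth <- nCov > 0 & !is.nan(overall) &
    markerMean < params$minDepthFrac * overall
  highMiss <- rowMeans(is.na(callsMat)) > params$maxMissing
  drop <- lowDepth | highMiss
  if (all(drop)) stop("all markers dropped by the quality filters")
  reason <- ifelse(lowDepth & highMiss, "LOW_DEPTH;HIGH_MISSING",
                   ifelse(lowDepth, "LOW_DEPTH", "HIGH_MISSING"))
  ids <- rownames(callsMat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(callsMat)))
  list(keep = which(!drop),
       dropLog = data.frame(row = which(drop),
                            markerId = ids[drop],
                            reason = reason[drop],
                            stringsAsFactors = FALSE, row.names = NULL))
}

#' Naive completion of remaining missing calls
#'
#' A deliberately simple stand-in for external imputation software run after
#' the block-based step: each missing cell is filled with the majority call
#' among its block neighbors at that marker; cells with no neighbors or a
#' neighbor tie fall through to the marker's population-majority allele;
#' population ties break toward REF. A marker missing in the whole
#' population is filled REF with a warning. The output has no missing cells.
#'
#' @param callsMat call matrix (markers x haplotypes).
#' @param lib a \code{\link{BlockLibrary}}.
#' @param markers marker annotation with \code{chrom}, \code{isSnp} and
#'   \code{chromIndex} columns aligned to the rows of \code{callsMat}
#'   (from \code{\link{markerInfo}}).
#' @return list with \code{calls} (complete matrix) and \code{completed}
#'   (logical matrix marking the cells filled here).
#' @export
naiveComplete <- function(callsMat, lib,
                          markers = data.frame(
                            chrom = rep("chr1", nrow(callsMat)),
                            isSnp = TRUE,
                            chromIndex = seq_len(nrow(callsMat)) - 1L)) {
  stopifnot(nrow(markers) == nrow(callsMat))
  haps <- colnames(callsMat)
  if (is.null(haps)) {
    haps <- sprintf("H%d", seq_len(ncol(callsMat)))
    colnames(callsMat) <- haps
  }
  out <- callsMat
  isAlt <- (callsMat == 1L) & !is.na(callsMat)
  isRef <- (callsMat == 0L) & !is.na(callsMat)
  # neighbor majority
  nbAlt <- matrix(0, nrow(callsMat), ncol(callsMat))
  nbRef <- matrix(0, nrow(callsMat), ncol(callsMat))
  for (ch in unique(markers$chrom[markers$isSnp])) {
    rows <- which(markers$isSnp & markers$chrom == ch)
    for (seg in .blockSegments(lib, ch, length(rows))) {
      if (!length(seg$blockIdx)) next
      nm <- .neighborMatrix(lib, seg$blockIdx, haps)
      N <- t(nm$neighbors * 1)
      sr <- rows[(seg$start + 1L):seg$end]
      nbAlt[sr, ] <- nbAlt[sr, ] + isAlt[sr, , drop = FALSE] %*% N
      nbRef[sr, ] <- nbRef[sr, ] + isRef[sr, , drop = FALSE] %*% N
    }
  }
  popAlt <- rowSums(isAlt)
  popRef <- rowSums(isRef)
  allMissing <- popAlt + popRef == 0
  if (any(allMissing & markers$isSnp))
    warning(sum(allMissing & markers$isSnp),
            " marker(s) missing population-wide; filled REF")
  popCall <- ifelse(popAlt > popRef, 1L, 0L)  # tie -> REF
  miss <- is.na(callsMat)
  fillNb <- miss & (nbAlt != nbRef)
  out[fillNb] <- ifelse(nbAlt > nbRef, 1L, 0L)[fillNb]
  fillPop <- miss & !fillNb
  out[fillPop] <- matrix(popCall, nrow(callsMat), ncol(callsMat))[fillPop]
  storage.mode(out) <- "integer"
  list(calls = out, completed = miss)
}

#' Run the full block-based calling step
#'
#' Composes \code{\link{mergeReads}}, \code{\link{callFromSupport}},
#' \code{\link{finalizeCalls}}, \code{\link{estimateDepth}},
#' \code{\link{filterMarkers}} and optionally \code{\link{naiveComplete}}.
#'
#' @param panel raw \code{\link{HaplotypePanel}}.
#' @param lib a \code{\link{BlockLibrary}}.
#' @param params list from \code{\link{hbParams}}.
#' @param complete also fill remaining missing cells via
#'   \code{\link{naiveComplete}}.
#' @return list with
#'   \describe{
#'     \item{\code{panel}}{the filtered panel with final calls (raw read
#'       counts retained);}
#'     \item{\code{depth}}{the \code{\linkS4class{DepthTrack}} restricted to
#'       retained markers;}
#'     \item{\code{provenance}}{character matrix over retained markers with
#'       labels \code{RAW_CALLED}/\code{HB_CALLED}/\code{COMPLETED}/
#'       \code{MISSING};}
#'     \item{\code{dropLog}}{dropped-marker log;}
#'     \item{\code{summary}}{pre/post missing fractions; \code{meanDepth},
#'       the mean per-haplotype depth estimate over covered cells;
#'       \code{meanMergedReads}, the mean weighted read count per covered
#'       cell (the pipeline-reported "average read-depth", which counts a
#'       line's own reads at the self-weight); marker counts.}
#'   }
#' @examples
#' toy <- toyExample()
#' res <- runHBStep(toy$panel, toy$library, complete = FALSE)
#' res$summary$postMissing < res$summary$preMissing
#' @export
runHBStep <- function(panel, lib, params = hbParams(), complete = FALSE) {
  s <- mergeReads(panel, lib, params)
  hb <- callFromSupport(s, params)
  fin <- finalizeCalls(hb, panel)
  dt <- estimateDepth(s)
  flt <- filterMarkers(fin$calls, dt, params)
  finalCalls <- fin$calls
  prov <- fin$provenance
  if (complete) {
    cmp <- naiveComplete(finalCalls, lib, markerInfo(panel))
    finalCalls <- cmp$calls
    prov[cmp$completed] <- "COMPLETED"
  }
  keep <- flt$keep
  outPanel <- .setCalls(panel, finalCalls)[keep, ]
  wTot <- (s@wRef + s@wAlt)[keep, , drop = FALSE]
  covKeep <- s@coveredCells[keep, , drop = FALSE]
  dm <- depthMatrix(dt)[keep, , drop = FALSE]
  hm <- colMeans(dm, na.rm = TRUE)
  hm[is.nan(hm)] <- NA_real_
  outDepth <- new("DepthTrack", depth = dm, hapMeans = hm,
                  markers = markerInfo(panel)[keep, , drop = FALSE])
  list(
    panel = outPanel,
    depth = outDepth,
    provenance = prov[keep, , drop = FALSE],
    dropLog = flt$dropLog,
    summary = list(
      preMissing = mean(is.na(calls(panel))),
      postMissing = mean(is.na(finalCalls[keep, , drop = FALSE])),
      meanDepth = if (all(is.na(dm))) NA_real_ else mean(dm, na.rm = TRUE),
      meanMergedReads = if (!any(covKeep)) NA_real_ else
        mean(wTot[covKeep]),  # includes the self-weighting of own reads
      coverage = mean(!is.na(dm)),
      markersIn = nrow(panel),
      markersOut = length(keep),
      markersDropped = nrow(panel) - length(keep)))
}
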